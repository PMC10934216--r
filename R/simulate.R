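# Synthetic alignment generator with planted SSRs and a ground-truth
# ledger. Backgrounds are i.i.d. bases rejection-sampled against
# accidental SSRs (the miner itself is the oracle), planted repeats sit at
# shared alignment columns across their carrier samples, repeat-count
# differences are realized as gap columns in the shorter samples, missing
# data as per-sample whole-locus dropout, and truncation as leading gap
# blocks cutting into a repeat. Every assembled fragment is re-mined and
# must reproduce exactly its planted SSR set before it is accepted, so the
# ledger is exact rather than probabilistic.

#' Default taxonomy of the emulated study design
#'
#' 29 samples across six genera of Ophioglossaceae (16 Botrychium from 15
#' labeled species, 2 Botrypus of one species, 1 Cheiroglossa, 1
#' Helminthostachys, 3 Ophioderma of one species, 6 Sceptridium: 3 named
#' species, two of them sampled twice, plus 2 genus-only samples).
#' Sample IDs are the sequencing IDs.
#'
#' @return Taxonomy data.frame (sample_id, species, genus, voucher,
#'   sequencing_id).
#' @export
default_taxonomy <- function() {
  rows <- matrix(c(
    "Botrychium acuminatum", "EW286", "P015 WG11",
    "Botrychium alaskense", "EW1083", "P03 WD06",
    "Botrychium alaskense salchakatense", "EW1082", "P03 WC06",
    "Botrychium angustisegmentum", "EW512", "P015 WA12",
    "Botrychium campestre", "EW638", "P015 WB12",
    "Botrychium echo", "EW999", "P015 WE12",
    "Botrychium hesperium", "EW1014", "P015 WF12",
    "Botrychium lanceolatum", "EW1081", "P03 WB06",
    "Botrychium lunaria", "BD160901", "P015 WG12",
    "Botrychium matricariifolium", "EW299", "P015 WH11",
    "Botrychium matricariifolium", "SF812", "P028 WD08",
    "Botrychium michiganense", "EW190", "P015 WF11",
    "Botrychium minganense", "EW85", "P015 WD11",
    "Botrychium neolunaria", "EW735", "P015 WC12",
    "Botrychium pallidum", "EW113", "P015 WE11",
    "Botrychium simplex", "EW791", "P015 WD12",
    "Botrypus virginianus", "Sundue 4021", "P055 WB10",
    "Botrypus virginianus", "EW1079", "P03 WA06",
    "Cheiroglossa palmata", "Jimenez 780", "P071 WF12",
    "Helminthostachys zeylanica", "Lee 530", "P069 WF05",
    "Ophioderma pendula", "2001-0045B", "P016 WH10",
    "Ophioderma pendula", "Ranker 1932", "P067 WA10",
    "Ophioderma pendula", "Testo sn", "P069 WH03",
    "Sceptridium biternatum", "Huey sn", "P072 WC08",
    "Sceptridium decompositum", "Sundue 4064", "P063 WA11",
    "Sceptridium multifidum", "SF814", "P028 WE08",
    "Sceptridium multifidum", "EW1084", "P03 WE06",
    "Sceptridium sp.", "SF816", "P028 WG08",
    "Sceptridium sp.", "Testo COL99", "P058 WH09"
  ), ncol = 3, byrow = TRUE)
  data.frame(
    sample_id = gsub(" ", "_", rows[, 3]),
    species = rows[, 1],
    genus = vapply(strsplit(rows[, 1], " "), `[[`, "", 1L),
    voucher = rows[, 2],
    sequencing_id = rows[, 3],
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 29 samples
#' with the [default_taxonomy()] genus structure, locus alignment lengths
#' drawn from 159-2228 bp, per-sample missing-data fractions spanning
#' 0.12-0.95, a small internal gap rate, and a planted-SSR plan of 10
#' unique / 20 shared / 30 polymorphic repeats including compounds and
#' truncations (see [default_plant_plan()]).
#'
#' @param taxonomy Taxonomy table; its samples are the simulated samples.
#' @param n_loci Number of loci.
#' @param locus_length_range Alignment length range in columns (bp).
#' @param missing_range Range of per-sample missing-data fractions.
#' @param gap_rate Per-column probability of an internal gap inside
#'   background blocks.
#' @param base_comp Named base composition for background sequence.
#' @param thresholds Mining thresholds the backgrounds are rejected
#'   against.
#' @param plant_plan Planted-SSR plan (list of entries); NULL builds the
#'   default plan at simulation time.
#' @param plan_counts Passed to [default_plant_plan()] when plant_plan is
#'   NULL: named vector (unique, shared, polymorphic).
#' @param n_compound,n_truncated Passed to [default_plant_plan()].
#' @param seed Mandatory RNG seed; the whole dataset is a pure function of
#'   the configuration.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(taxonomy = default_taxonomy(),
                              n_loci = 100L,
                              locus_length_range = c(159L, 2228L),
                              missing_range = c(0.12, 0.95),
                              gap_rate = 0.02,
                              base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                              thresholds = default_thresholds(),
                              plant_plan = NULL,
                              plan_counts = c(unique = 10L, shared = 20L,
                                              polymorphic = 30L),
                              n_compound = 6L, n_truncated = 5L,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  taxonomy <- validate_taxonomy(taxonomy)
  stopifnot(n_loci >= 1L, locus_length_range[1L] >= 60L,
            locus_length_range[1L] <= locus_length_range[2L],
            all(missing_range >= 0), all(missing_range < 1),
            gap_rate >= 0, gap_rate < 0.5)
  structure(
    list(taxonomy = taxonomy, n_loci = as.integer(n_loci),
         locus_length_range = as.integer(locus_length_range),
         missing_range = missing_range, gap_rate = gap_rate,
         base_comp = base_comp / sum(base_comp),
         thresholds = validate_thresholds(thresholds),
         plant_plan = plant_plan, plan_counts = plan_counts,
         n_compound = as.integer(n_compound),
         n_truncated = as.integer(n_truncated),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

random_motif <- function(k, bases = c("A", "C", "G", "T")) {
  repeat {
    m <- paste(sample(bases, k, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

# class sampling weights shaped like observed flanking-region composition
# (dinucleotides dominant, then tetra-, tri-, mono-, hexa-, penta-)
CLASS_WEIGHTS <- c(138, 810, 178, 256, 27, 66)

# Generator-side classification arithmetic for the ledger: category and
# tier expected from the observed (post-truncation) repeat counts.
expected_classification <- function(carriers, obs_repeats, truncated,
                                    taxonomy) {
  ti <- taxonomy[match(carriers, taxonomy$sample_id), ]
  sp <- species_key(ti$species, ti$sample_id)
  gn <- ti$genus
  n_counts <- length(unique(obs_repeats))
  if (length(carriers) == 1L) {
    list(category = "unique", tier = "not_applicable", edge_artifact = FALSE)
  } else if (n_counts >= 2L) {
    list(category = "polymorphic",
         tier = narrowest_differing_rank(obs_repeats, sp, gn),
         edge_artifact = any(truncated) &&
           length(unique(obs_repeats[!truncated])) <= 1L)
  } else {
    tier <- if (length(unique(sp)) == 1L) "within_species"
    else if (length(unique(gn)) == 1L) "within_genus"
    else "across_genera"
    list(category = "shared", tier = tier, edge_artifact = FALSE)
  }
}

# A compound motif pair is usable only if mining the concatenation yields
# exactly the two planted components, for every carrier's repeat combo.
compound_pair_ok <- function(m1, r1, m2, r2, thr) {
  for (i in seq_along(r1)) {
    s <- paste0(strrep(m1, r1[[i]]), strrep(m2, r2[[i]]))
    hit <- find_perfect_ssrs(s, thr)
    ok <- nrow(hit) == 2L && hit$motif[1L] == m1 && hit$repeats[1L] == r1[[i]] &&
      hit$motif[2L] == m2 && hit$repeats[2L] == r2[[i]]
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Build the default planted-SSR plan
#'
#' Chooses carriers, motifs and repeat counts realizing the requested
#' numbers of unique, shared and polymorphic SSRs, cycling the taxonomic
#' tiers (within species / within genus / across genera) for the latter
#' two. A subset of multi-carrier entries receives a strictly adjacent
#' compound partner (pairs are pre-validated: mining the concatenation
#' must reproduce both components), and a subset of shared entries gets
#' one carrier edge-truncated by whole motif copies, which turns the
#' observed group polymorphic with the edge-artifact flag.
#'
#' Uses the RNG; call inside [simulate_dataset()] or after set.seed().
#'
#' @param taxonomy Taxonomy table.
#' @param counts Named vector: numbers of unique/shared/polymorphic base
#'   entries.
#' @param n_compound Entries to extend into compound SSRs.
#' @param n_truncated Shared entries to edge-truncate in one carrier.
#' @param thresholds Mining thresholds.
#' @return List of plan entries (ssr_id, unit_id, unit_pos, motif, class,
#'   carriers, repeats, truncate, category, tier, edge_artifact).
#' @export
default_plant_plan <- function(taxonomy,
                               counts = c(unique = 10L, shared = 20L,
                                          polymorphic = 30L),
                               n_compound = 6L, n_truncated = 5L,
                               thresholds = default_thresholds()) {
  thr <- validate_thresholds(thresholds)
  tax <- validate_taxonomy(taxonomy)
  sp <- species_key(tax$species, tax$sample_id)
  multi_sp <- names(which(table(sp) >= 2L))
  genus_tab <- table(tax$genus,
                     factor(sp, levels = unique(sp)))
  multi_genus <- rownames(genus_tab)[apply(genus_tab > 0, 1L, sum) >= 2L]
  genera <- unique(tax$genus)
  if (length(multi_sp) == 0L || length(multi_genus) == 0L ||
      length(genera) < 2L) {
    stop(paste("taxonomy must contain a species with >= 2 samples, a",
               "genus with >= 2 species and >= 2 genera to realize all",
               "tiers"), call. = FALSE)
  }

  draw_class <- function() sample(1:6, 1L, prob = CLASS_WEIGHTS)
  base_reps <- function(k) thr[[k]] + sample(0:5, 1L)

  pick_carriers <- function(tier, polymorphic) {
    if (tier == "within_species") {
      s <- sample(multi_sp, 1L)
      ids <- tax$sample_id[sp == s]
      sample(ids, 2L)
    } else if (tier == "within_genus") {
      g <- sample(multi_genus, 1L)
      spp <- unique(sp[tax$genus == g])
      n_sp <- sample(2:min(4L, length(spp)), 1L)
      chosen <- sample(spp, n_sp)
      if (polymorphic) {
        # one sample per species so the narrowest differing rank is genus
        vapply(chosen, function(s) sample(tax$sample_id[sp == s], 1L), "")
      } else {
        unlist(lapply(chosen, function(s) tax$sample_id[sp == s]))
      }
    } else {
      n_g <- sample(2:min(4L, length(genera)), 1L)
      chosen <- sample(genera, n_g)
      vapply(chosen, function(g) sample(tax$sample_id[tax$genus == g], 1L), "")
    }
  }

  entries <- list()
  add_entry <- function(category, tier, carriers, repeats, truncate = NULL) {
    k <- draw_class()
    motif <- random_motif(k)
    if (is.null(truncate)) truncate <- stats::setNames(
      integer(length(carriers)), carriers)
    id <- sprintf("ssr%03d", length(entries) + 1L)
    cls <- expected_classification(carriers, repeats - truncate,
                                   truncate > 0L, tax)
    entries[[length(entries) + 1L]] <<- list(
      ssr_id = id, unit_id = id, unit_pos = 1L,
      motif = motif, class = k, carriers = carriers,
      repeats = stats::setNames(repeats, carriers), truncate = truncate,
      intended_category = category,
      category = cls$category, tier = cls$tier,
      edge_artifact = cls$edge_artifact
    )
  }

  for (i in seq_len(counts[["unique"]])) {
    carrier <- sample(tax$sample_id, 1L)
    add_entry("unique", "not_applicable", carrier,
              stats::setNames(sample(0:5, 1L), carrier))
  }
  tiers <- c("within_species", "within_genus", "across_genera")
  for (i in seq_len(counts[["shared"]])) {
    tier <- tiers[(i - 1L) %% 3L + 1L]
    carriers <- pick_carriers(tier, polymorphic = FALSE)
    r <- thr[[3L]] + sample(2:5, 1L)  # placeholder; rescaled below
    add_entry("shared", tier, carriers,
              rep(r, length(carriers)))
  }
  for (i in seq_len(counts[["polymorphic"]])) {
    tier <- tiers[(i - 1L) %% 3L + 1L]
    carriers <- pick_carriers(tier, polymorphic = TRUE)
    offs <- sample(0:3, length(carriers), replace = TRUE)
    while (length(unique(offs)) < 2L) {
      offs <- sample(0:3, length(carriers), replace = TRUE)
    }
    add_entry("polymorphic", tier, carriers, offs)  # rescaled below
  }

  # rescale repeat counts to the entry's own class threshold (class is
  # drawn inside add_entry, so repeats passed in are offsets/placeholders)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    base <- thr[[e$class]] + 2L
    if (e$intended_category == "polymorphic") {
      e$repeats <- base + e$repeats
    } else {
      e$repeats[] <- base + (e$repeats[1L] %% 4L)
    }
    cls <- expected_classification(e$carriers, e$repeats - e$truncate,
                                   e$truncate > 0L, tax)
    e$category <- cls$category; e$tier <- cls$tier
    e$edge_artifact <- cls$edge_artifact
    entries[[i]] <- e
  }

  # truncations: shared entries, first carrier loses leading motif copies
  shared_idx <- which(vapply(entries, function(e)
    e$intended_category == "shared", TRUE))
  for (i in utils::head(shared_idx, n_truncated)) {
    e <- entries[[i]]
    cut <- pmin(2L, e$repeats[1L] - thr[[e$class]])
    if (cut < 1L) next
    e$truncate[1L] <- cut
    cls <- expected_classification(e$carriers, e$repeats - e$truncate,
                                   e$truncate > 0L, tax)
    e$category <- cls$category; e$tier <- cls$tier
    e$edge_artifact <- cls$edge_artifact
    entries[[i]] <- e
  }

  # compounds: extend multi-carrier, untruncated entries with an adjacent
  # partner of a different, pre-validated motif
  elig <- which(vapply(entries, function(e)
    length(e$carriers) >= 2L && all(e$truncate == 0L), TRUE))
  for (i in utils::head(elig, n_compound)) {
    e <- entries[[i]]
    for (try in 1:50) {
      k2 <- draw_class()
      m2 <- random_motif(k2)
      if (m2 %in% motif_rotations(e$motif)) next
      r2 <- stats::setNames(rep(thr[[k2]] + sample(0:3, 1L),
                                length(e$carriers)), e$carriers)
      if (compound_pair_ok(e$motif, e$repeats, m2, r2, thr)) break
      m2 <- NULL
    }
    if (is.null(m2)) next
    cls <- expected_classification(e$carriers, r2,
                                   rep(FALSE, length(e$carriers)), tax)
    id <- sprintf("ssr%03d", length(entries) + 1L)
    entries[[length(entries) + 1L]] <- list(
      ssr_id = id, unit_id = e$unit_id, unit_pos = 2L,
      motif = m2, class = k2, carriers = e$carriers,
      repeats = r2, truncate = stats::setNames(
        integer(length(e$carriers)), e$carriers),
      intended_category = cls$category,
      category = cls$category, tier = cls$tier, edge_artifact = FALSE
    )
  }
  entries
}

# SSR-free background fragment of given length; forbid_first/forbid_last
# constrain the edge residues so they cannot extend an adjacent planted
# repeat.
ssr_free_fragment <- function(len, base_comp, thr,
                              forbid_first = NULL, forbid_last = NULL) {
  bases <- names(base_comp)
  if (len == 0L) return(character(0))
  repeat {
    x <- sample(bases, len, replace = TRUE, prob = base_comp)
    if (!is.null(forbid_first) && x[1L] %in% forbid_first) {
      x[1L] <- sample(setdiff(bases, forbid_first), 1L)
    }
    if (!is.null(forbid_last) && x[len] %in% forbid_last) {
      x[len] <- sample(setdiff(bases, forbid_last), 1L)
    }
    if (len < 12L ||
        nrow(find_perfect_ssrs(paste(x, collapse = ""), thr)) == 0L) {
      return(x)
    }
  }
}

#' Simulate a multi-sample, multi-locus alignment dataset
#'
#' Generates per-locus alignments with planted SSRs of known category and
#' tier, and the matching truth ledger. Fully reproducible: the same
#' configuration (including seed) yields byte-identical output. Every
#' assembled fragment is verified by re-mining: the detected SSR set must
#' equal the planted one exactly (background is re-drawn otherwise), so
#' recovery tests can demand exact agreement.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, per-locus FASTA files
#'   (\code{L<n>.fasta}), \code{taxonomy.tsv}, \code{ledger_ssrs.tsv} and
#'   \code{ledger_members.tsv} are written there.
#' @return List: \code{alignments} (named list of locus_alignment),
#'   \code{taxonomy}, \code{ledger} (list with per-SSR \code{ssrs} and
#'   per-carrier \code{members} data.frames), \code{config}.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tax <- config$taxonomy
  thr <- config$thresholds
  samples <- tax$sample_id
  n_loci <- config$n_loci
  lens <- sample(seq(config$locus_length_range[1L],
                     config$locus_length_range[2L]),
                 n_loci, replace = TRUE)
  plan <- config$plant_plan
  if (is.null(plan)) {
    plan <- default_plant_plan(tax, config$plan_counts, config$n_compound,
                               config$n_truncated, thr)
  }
  units <- split(plan, vapply(plan, function(e) e$unit_id, ""))
  units <- units[order(vapply(units, function(u) u[[1L]]$ssr_id, ""))]

  # assign each unit its own locus, largest requirements to longest loci
  unit_width <- vapply(units, function(u)
    sum(vapply(u, function(e) max(e$repeats) * e$class, 0)), 0)
  if (length(units) > n_loci) {
    stop("more planted units than loci", call. = FALSE)
  }
  locus_order <- order(-lens)
  unit_locus <- stats::setNames(
    locus_order[rank(-unit_width, ties.method = "first")], names(units))
  if (any(lens[unit_locus] < unit_width + 60)) {
    bad <- names(units)[which(lens[unit_locus] < unit_width + 60)[1L]]
    stop(sprintf("unplaceable SSR unit %s: locus too short", bad),
         call. = FALSE)
  }
  locus_unit <- rep(NA_character_, n_loci)
  locus_unit[unit_locus] <- names(units)

  miss_frac <- stats::setNames(
    stats::runif(length(samples), config$missing_range[1L],
                 config$missing_range[2L]), samples)

  alignments <- vector("list", n_loci)
  member_rows <- list()
  for (li in seq_len(n_loci)) {
    locus_id <- paste0("L", li)
    L <- lens[li]
    unit <- if (!is.na(locus_unit[li])) units[[locus_unit[li]]] else NULL
    lay <- locus_layout(L, unit)
    rows <- matrix("-", nrow = length(samples), ncol = L,
                   dimnames = list(samples, NULL))
    for (si in seq_along(samples)) {
      s <- samples[si]
      carrier <- !is.null(unit) &&
        s %in% unit[[1L]]$carriers
      if (!carrier && stats::runif(1L) < miss_frac[[s]]) next  # absent
      rows[si, ] <- build_verified_row(s, locus_id, lay, unit, config)
    }
    alignments[[li]] <- new_locus_alignment(
      locus_id, apply(rows, 1L, paste, collapse = ""))
    if (!is.null(unit)) {
      for (e in unit) {
        bs <- lay$block_start[[e$ssr_id]]
        for (s in e$carriers) {
          cut <- e$truncate[[s]]
          r <- e$repeats[[s]]
          aln_start <- bs + cut * e$class
          aln_end <- bs + r * e$class - 1L
          row <- rows[s, ]
          dstart <- sum(row[seq_len(aln_start - 1L)] != "-") + 1L
          member_rows[[length(member_rows) + 1L]] <- data.frame(
            ssr_id = e$ssr_id, locus_id = locus_id, sample_id = s,
            motif = e$motif, class = e$class,
            planted_repeats = r, truncated = cut > 0L,
            expected_repeats = r - cut,
            expected_start = dstart,
            expected_aln_start = aln_start, expected_aln_end = aln_end,
            compound_id = if (length(unit) > 1L) e$unit_id
            else NA_character_,
            category = e$category, tier = e$tier,
            edge_artifact = e$edge_artifact,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  names(alignments) <- paste0("L", seq_len(n_loci))
  members <- if (length(member_rows) > 0L) do.call(rbind, member_rows)
  else data.frame()
  ssrs <- do.call(rbind, lapply(plan, function(e) data.frame(
    ssr_id = e$ssr_id, motif = e$motif, class = e$class,
    n_carriers = length(e$carriers),
    compound_id = if (sum(vapply(plan, function(x)
      x$unit_id == e$unit_id, TRUE)) > 1L) e$unit_id else NA_character_,
    intended_category = e$intended_category,
    category = e$category, tier = e$tier,
    edge_artifact = e$edge_artifact, stringsAsFactors = FALSE)))
  ssrs$locus_id <- members$locus_id[match(ssrs$ssr_id, members$ssr_id)]
  sim <- list(alignments = alignments, taxonomy = tax,
              ledger = list(ssrs = ssrs, members = members),
              config = config)
  if (!is.null(out_dir)) write_simulated_dataset(sim, out_dir)
  sim
}

# Column layout of one locus: background blocks around the unit's SSR
# sub-blocks (one sub-block per compound component, strictly adjacent).
locus_layout <- function(L, unit) {
  if (is.null(unit)) {
    return(list(blocks = list(list(type = "bg", start = 1L, end = L)),
                block_start = list()))
  }
  widths <- vapply(unit, function(e) max(e$repeats) * e$class, 0)
  sumw <- sum(widths)
  wl <- max(30L, as.integer(floor((L - sumw) / 2)))
  blocks <- list(list(type = "bg", start = 1L, end = wl))
  block_start <- list()
  pos <- wl + 1L
  for (i in seq_along(unit)) {
    e <- unit[[i]]
    blocks[[length(blocks) + 1L]] <- list(
      type = "ssr", start = pos, end = pos + widths[i] - 1L, entry = i)
    block_start[[e$ssr_id]] <- pos
    pos <- pos + widths[i]
  }
  blocks[[length(blocks) + 1L]] <- list(type = "bg", start = pos, end = L)
  list(blocks = blocks, block_start = block_start)
}

# Assemble one sample's aligned row and verify it by mining; background is
# re-drawn until the mined SSR set equals the planted one exactly.
build_verified_row <- function(s, locus_id, lay, unit, config) {
  thr <- config$thresholds
  carrier <- !is.null(unit) && s %in% unit[[1L]]$carriers
  expected <- NULL
  cut_col <- 0L
  if (carrier) {
    exp_rows <- list()
    for (e in unit) {
      bs <- lay$block_start[[e$ssr_id]]
      cut <- e$truncate[[s]]
      r <- e$repeats[[s]]
      if (cut > 0L) cut_col <- max(cut_col, bs + cut * e$class - 1L)
      exp_rows[[length(exp_rows) + 1L]] <- data.frame(
        motif = e$motif, repeats = r - cut,
        aln_start = bs + cut * e$class, aln_end = bs + r * e$class - 1L,
        stringsAsFactors = FALSE)
    }
    expected <- do.call(rbind, exp_rows)
    expected <- expected[order(expected$aln_start), , drop = FALSE]
  } else {
    expected <- data.frame(motif = character(0), repeats = integer(0),
                           aln_start = integer(0), aln_end = integer(0))
  }

  for (attempt in 1:25) {
    row <- rep("-", lay$blocks[[length(lay$blocks)]]$end)
    for (bi in seq_along(lay$blocks)) {
      b <- lay$blocks[[bi]]
      w <- b$end - b$start + 1L
      if (w <= 0L) next
      if (b$type == "bg") {
        forbid_last <- forbid_first <- NULL
        if (carrier && bi < length(lay$blocks)) {
          m <- unit[[lay$blocks[[bi + 1L]]$entry]]$motif
          forbid_last <- substr(m, nchar(m), nchar(m))
        }
        if (carrier && bi > 1L) {
          m <- unit[[lay$blocks[[bi - 1L]]$entry]]$motif
          forbid_first <- substr(m, 1L, 1L)
        }
        n_gap <- stats::rbinom(1L, w, config$gap_rate)
        frag <- ssr_free_fragment(w - n_gap, config$base_comp, thr,
                                  forbid_first, forbid_last)
        cells <- rep("-", w)
        if (w - n_gap > 0L) {
          keep <- sort(sample.int(w, w - n_gap))
          cells[keep] <- frag
        }
        row[b$start:b$end] <- cells
      } else if (carrier) {
        e <- unit[[b$entry]]
        r <- e$repeats[[s]]
        motif_chars <- strsplit(e$motif, "", fixed = TRUE)[[1L]]
        filled <- rep(motif_chars, r)
        row[b$start:(b$start + length(filled) - 1L)] <- filled
      }
      # non-carrier SSR blocks stay all-gap
    }
    if (cut_col > 0L) row[seq_len(cut_col)] <- "-"
    seq <- degap(paste(row, collapse = ""), s, locus_id)
    mined <- find_perfect_ssrs(seq, thr)
    sig <- function(df) paste(df$motif, df$repeats, df$aln_start,
                              df$aln_end, sep = ":", collapse = ";")
    if (sig(mined) == sig(expected)) return(row)
  }
  stop(sprintf("could not realize planted SSRs for sample %s in %s",
               s, locus_id), call. = FALSE)
}

#' Write a simulated dataset to disk
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in sim$alignments) {
    set <- Biostrings::BStringSet(aln$sequences)
    Biostrings::writeXStringSet(
      set, file.path(dir, paste0(aln$locus_id, ".fasta")))
  }
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  utils::write.table(sim$ledger$ssrs, file.path(dir, "ledger_ssrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ledger$members, file.path(dir, "ledger_members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Bundled miniature dataset for examples and hand checks
#'
#' A deterministic 5-sample, 10-locus dataset with one planted SSR of each
#' kind: a unique repeat, shared repeats at the species/genus/family
#' tiers, repeat-count polymorphisms, a two-component compound and an
#' edge-truncated case. Expected mining and classification tables for it
#' are stored under \code{inst/extdata} and checked in the test suite.
#'
#' @param out_dir Optional directory to write the dataset to.
#' @return As [simulate_dataset()].
#' @export
fixture_small <- function(out_dir = NULL) {
  tax <- default_taxonomy()
  tax <- tax[tax$sample_id %in% c("P015_WH11", "P028_WD08", "P015_WE12",
                                  "P03_WA06", "P072_WC08"), ]
  mk <- function(ssr_id, unit_id, unit_pos, motif, carriers, repeats,
                 truncate = NULL, intended = NULL) {
    if (is.null(truncate)) truncate <- stats::setNames(
      integer(length(carriers)), carriers)
    cls <- expected_classification(carriers, repeats - truncate,
                                   truncate > 0L, tax)
    list(ssr_id = ssr_id, unit_id = unit_id, unit_pos = unit_pos,
         motif = motif, class = nchar(motif), carriers = carriers,
         repeats = stats::setNames(repeats, carriers), truncate = truncate,
         intended_category = if (is.null(intended)) cls$category
         else intended,
         category = cls$category, tier = cls$tier,
         edge_artifact = cls$edge_artifact)
  }
  both_matri <- c("P015_WH11", "P028_WD08")
  plan <- list(
    mk("ssr001", "ssr001", 1L, "AG", "P015_WE12", c(P015_WE12 = 8L)),
    mk("ssr002", "ssr002", 1L, "GAT", both_matri, c(5L, 5L)),
    mk("ssr003", "ssr003", 1L, "GCAT",
       c("P015_WH11", "P03_WA06", "P072_WC08"), c(3L, 3L, 3L)),
    mk("ssr004", "ssr004", 1L, "AC", both_matri, c(6L, 9L)),
    mk("ssr005", "ssr005", 1L, "T",
       c("P015_WE12", "P072_WC08"), c(12L, 14L)),
    mk("ssr006", "ssr006", 1L, "GTAT",
       c("P03_WA06", "P072_WC08"), c(3L, 3L)),
    mk("ssr007", "ssr006", 2L, "GT",
       c("P03_WA06", "P072_WC08"), c(12L, 12L)),
    mk("ssr008", "ssr008", 1L, "AAG",
       c("P015_WH11", "P015_WE12"), c(6L, 6L),
       truncate = c(P015_WH11 = 2L, P015_WE12 = 0L), intended = "shared")
  )
  cfg <- simulation_config(
    taxonomy = tax, n_loci = 10L, locus_length_range = c(200L, 600L),
    missing_range = c(0.05, 0.25), gap_rate = 0.02,
    plant_plan = plan, seed = 104729L)
  simulate_dataset(cfg, out_dir = out_dir)
}
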