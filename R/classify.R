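# Cross-sample SSR grouping in alignment-column space and classification
# into unique / shared / polymorphic at taxonomic tiers.
#
# Two SSRs from different samples belong to the same locus group when
# their alignment intervals overlap by at least one column AND their
# motifs are cyclic rotations of one another (equal class). Rotation
# equivalence only: reverse complements are deliberately NOT equated, so
# AG, GA and TC groups stay distinct (a complement-aware view exists in
# the summaries, never in classification).

species_key <- function(species, sample_id) {
  # samples identified to genus only ("Sceptridium sp.") count as distinct
  # species for tier computation
  genus_only <- grepl("(^|\\s)sp\\.?$", species)
  ifelse(genus_only, paste(species, sample_id), species)
}

#' Group SSRs occupying the same aligned interval
#'
#' Transitive closure of the relation "alignment intervals overlap by >= 1
#' column and motifs are rotation-equivalent", computed per locus. SSRs
#' with non-equivalent motifs at the same interval form separate groups.
#'
#' @param ssrs data.frame of SSRs (any number of loci/samples) carrying
#'   aln_start/aln_end; a \code{truncated} column is used if present
#'   (falling back to \code{at_edge}).
#' @return List: \code{members} (the input plus group_id and
#'   overlap_fraction, the fraction of the group interval each member
#'   covers, for audit), and \code{groups} (one row per group: group_id,
#'   locus_id, aln_start, aln_end, class, motifs present, n_members,
#'   n_samples, n_distinct_repeat_counts, any_truncated).
#' @export
group_by_locus <- function(ssrs) {
  n <- nrow(ssrs)
  trunc <- if (!is.null(ssrs$truncated)) ssrs$truncated
  else if (!is.null(ssrs$at_edge)) ssrs$at_edge
  else rep(FALSE, n)
  ssrs$truncated <- trunc
  if (n == 0L) {
    return(list(members = cbind(ssrs, group_id = character(0),
                                overlap_fraction = numeric(0)),
                groups = data.frame()))
  }
  rkey <- rotation_key(ssrs$motif)
  part <- paste(ssrs$locus_id, ssrs$class, rkey, sep = "\r")
  group_id <- character(n)
  for (idx in split(seq_len(n), part)) {
    idx <- idx[order(ssrs$aln_start[idx])]
    cur <- 0L; cur_end <- -Inf
    for (i in idx) {
      if (ssrs$aln_start[i] > cur_end) cur <- cur + 1L
      group_id[i] <- sprintf("%s|%s|g%d", ssrs$locus_id[i], rkey[i], cur)
      cur_end <- max(cur_end, ssrs$aln_end[i])
    }
  }
  ssrs$group_id <- group_id
  gsplit <- split(seq_len(n), group_id)
  groups <- do.call(rbind, lapply(names(gsplit), function(g) {
    i <- gsplit[[g]]
    data.frame(
      group_id = g, locus_id = ssrs$locus_id[i[1L]],
      aln_start = min(ssrs$aln_start[i]), aln_end = max(ssrs$aln_end[i]),
      class = ssrs$class[i[1L]],
      motifs = paste(sort(unique(ssrs$motif[i])), collapse = ","),
      n_members = length(i),
      n_samples = length(unique(ssrs$sample_id[i])),
      n_distinct_repeat_counts = length(unique(ssrs$repeats[i])),
      any_truncated = any(ssrs$truncated[i]),
      stringsAsFactors = FALSE
    )
  }))
  width <- stats::setNames(groups$aln_end - groups$aln_start + 1,
                           groups$group_id)
  ssrs$overlap_fraction <-
    (ssrs$aln_end - ssrs$aln_start + 1) / width[ssrs$group_id]
  # locale-independent ordering so written tables are byte-stable
  groups <- groups[order(groups$locus_id, groups$aln_start, groups$class,
                         groups$motifs, method = "radix"), , drop = FALSE]
  rownames(groups) <- NULL
  list(members = ssrs, groups = groups)
}

#' Classify one SSR locus group
#'
#' Category: unique when only one sample carries the SSR; polymorphic when
#' two or more samples carry it with at least two distinct repeat counts;
#' shared when two or more samples carry it with identical repeat counts.
#' Tier: for shared groups, the narrowest taxonomic rank (species < genus
#' < across genera) containing all members; for polymorphic groups, the
#' narrowest rank containing at least two members with differing repeat
#' counts; not_applicable for unique groups. A polymorphic group whose
#' repeat-count variation disappears once edge-truncated members are set
#' aside is flagged \code{edge_artifact}: the "polymorphism" is probably
#' an incomplete repeat at a fragment edge.
#'
#' @param members data.frame with sample_id, repeats and truncated columns
#'   (the rows of one group).
#' @param taxonomy Taxonomy table covering all member samples.
#' @return One-row data.frame: category, tier, n_samples,
#'   n_distinct_repeat_counts, edge_artifact.
#' @export
classify_group <- function(members, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  miss <- setdiff(members$sample_id, taxonomy$sample_id)
  if (length(miss) > 0L) {
    stop(sprintf("sample(s) missing from taxonomy: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ti <- taxonomy[match(members$sample_id, taxonomy$sample_id), ]
  sp <- species_key(ti$species, ti$sample_id)
  gn <- ti$genus
  n_samples <- length(unique(members$sample_id))
  n_counts <- length(unique(members$repeats))
  trunc <- if (!is.null(members$truncated)) members$truncated
  else rep(FALSE, nrow(members))

  if (n_samples == 1L) {
    category <- "unique"; tier <- "not_applicable"
  } else if (n_counts >= 2L) {
    category <- "polymorphic"
    tier <- narrowest_differing_rank(members$repeats, sp, gn)
  } else {
    category <- "shared"
    tier <- if (length(unique(sp)) == 1L) "within_species"
    else if (length(unique(gn)) == 1L) "within_genus"
    else "across_genera"
  }
  edge_artifact <- category == "polymorphic" && any(trunc) &&
    length(unique(members$repeats[!trunc])) <= 1L
  data.frame(category = category, tier = tier, n_samples = n_samples,
             n_distinct_repeat_counts = n_counts,
             edge_artifact = edge_artifact, stringsAsFactors = FALSE)
}

# narrowest rank containing two members with differing repeat counts
narrowest_differing_rank <- function(repeats, sp, gn) {
  differs_within <- function(key) {
    any(vapply(split(repeats, key),
               function(r) length(unique(r)) > 1L, TRUE))
  }
  if (differs_within(sp)) "within_species"
  else if (differs_within(gn)) "within_genus"
  else "across_genera"
}

#' Classify every group of a grouping
#'
#' @param grouping Result of [group_by_locus()].
#' @param taxonomy Taxonomy table.
#' @return \code{grouping$groups} with category, tier, edge_artifact
#'   columns appended.
#' @export
classify_groups <- function(grouping, taxonomy) {
  groups <- grouping$groups
  if (nrow(groups) == 0L) return(groups)
  members <- grouping$members
  cls <- do.call(rbind, lapply(groups$group_id, function(g) {
    classify_group(members[members$group_id == g, , drop = FALSE], taxonomy)
  }))
  cbind(groups[, setdiff(names(groups),
                         c("n_samples", "n_distinct_repeat_counts"))], cls)
}

#' Tally classifications by category, tier and motif class
#'
#' SSR-level counts (each member SSR counted once), group counts, distinct
#' loci and distinct samples per category x tier x motif class, plus
#' category-level totals. SSR counts partition the input: unique + shared
#' + polymorphic = total.
#'
#' @param classified Result of [classify_groups()].
#' @param grouping The matching [group_by_locus()] result.
#' @return List with \code{by_class} (category/tier/class rows),
#'   \code{by_category} (category totals) and \code{total_ssrs}.
#' @export
classification_report <- function(classified, grouping) {
  members <- grouping$members
  if (nrow(members) == 0L) {
    return(list(by_class = data.frame(), by_category = data.frame(
      category = c("unique", "shared", "polymorphic"), n_ssrs = 0L,
      n_groups = 0L, n_loci = 0L, n_samples = 0L), total_ssrs = 0L))
  }
  gi <- match(members$group_id, classified$group_id)
  members$category <- classified$category[gi]
  members$tier <- classified$tier[gi]
  agg <- function(df, keys) {
    parts <- split(seq_len(nrow(df)), df[keys], drop = TRUE, sep = "\r")
    do.call(rbind, lapply(parts, function(i) {
      row <- df[i[1L], keys, drop = FALSE]
      row$n_ssrs <- length(i)
      row$n_groups <- length(unique(df$group_id[i]))
      row$n_loci <- length(unique(df$locus_id[i]))
      row$n_samples <- length(unique(df$sample_id[i]))
      row
    }))
  }
  by_class <- agg(members, c("category", "tier", "class"))
  by_class <- by_class[order(match(by_class$category,
                                   c("unique", "shared", "polymorphic")),
                             match(by_class$tier,
                                   c("within_species", "within_genus",
                                     "across_genera", "not_applicable")),
                             by_class$class), , drop = FALSE]
  by_cat <- agg(members, "category")
  for (cat in c("unique", "shared", "polymorphic")) {
    if (!cat %in% by_cat$category) {
      by_cat <- rbind(by_cat, data.frame(
        category = cat, n_ssrs = 0L, n_groups = 0L, n_loci = 0L,
        n_samples = 0L, stringsAsFactors = FALSE))
    }
  }
  ord <- match(by_cat$category, c("unique", "shared", "polymorphic"))
  by_cat <- by_cat[order(ord), , drop = FALSE]
  rownames(by_class) <- rownames(by_cat) <- NULL
  list(by_class = by_class, by_category = by_cat,
       total_ssrs = nrow(members))
}
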