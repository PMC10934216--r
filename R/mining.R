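# Perfect-SSR detection on degapped sequences, MISA-compatible thresholds,
# strict zero-interruption compounding, and the exon-subtraction step that
# isolates flanking-region repeats.
#
# Detection model: a perfect SSR is a maximal run of a primitive 1-6 bp
# motif with at least the class's minimum number of complete repetitions.
# Runs are found per period k as maximal stretches where s[i] == s[i+k];
# the reported motif is read at the run start (no rotation folding), the
# reported end is the last complete motif copy (partial trailing units are
# not counted), and runs are broken by 'N' and by sequence ends.
#
# Where maximal runs of different motifs overlap (MISA's "shared
# nucleotide" compound notation, e.g. (GTAT)2(GTA<T>G)(TG)12), the
# overlapping cluster is re-segmented into the fewest adjacent perfect
# runs each meeting its threshold - the normalized reading (GTAT)3(GT)12 -
# so the miner plus merge_compound() emit clean compounds directly.

#' Find perfect SSRs in a degapped sequence
#'
#' @param seq A \code{sample_sequence} from [degap()], or a plain character
#'   scalar over A/C/G/T/N (treated as an ungapped fragment).
#' @param thresholds Minimum repeat counts per motif class, see
#'   [default_thresholds()].
#' @return data.frame with one row per SSR: sample_id, locus_id, motif,
#'   class, repeats, start, end (degapped, 1-based inclusive), length_bp,
#'   aln_start, aln_end (alignment columns via the colmap), at_edge (run
#'   touches the first or last residue of the fragment). Sorted by start.
#'   Reported SSRs never overlap; components of a normalized overlap
#'   cluster come out as adjacent rows that [merge_compound()] will join.
#' @examples
#' find_perfect_ssrs(paste0(strrep("GTAT", 3), strrep("GT", 12)))
#' @export
find_perfect_ssrs <- function(seq, thresholds = default_thresholds()) {
  if (is.character(seq) && length(seq) == 1L) {
    seq <- degap(seq, NA_character_, NA_character_)
  }
  stopifnot(inherits(seq, "sample_sequence"))
  thresholds <- validate_thresholds(thresholds)
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) return(empty_ssr_table())

  cand <- enumerate_runs(chars, thresholds)
  picked <- resolve_overlaps(cand, chars, thresholds)
  if (nrow(picked) == 0L) return(empty_ssr_table())

  picked <- picked[order(picked$start), , drop = FALSE]
  data.frame(
    sample_id = seq$sample_id, locus_id = seq$locus_id,
    motif = picked$motif, class = picked$class, repeats = picked$repeats,
    start = picked$start, end = picked$end,
    length_bp = picked$end - picked$start + 1L,
    aln_start = seq$colmap[picked$start], aln_end = seq$colmap[picked$end],
    at_edge = picked$start == 1L | picked$end == n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Maximal periodic runs meeting thresholds, over N-free segments.
# Returns data.frame: start, end (complete copies only), ext_end (last
# character of the periodic stretch, including partial units), class,
# repeats, motif.
enumerate_runs <- function(chars, thr) {
  n <- length(chars)
  segs <- n_free_segments(chars)
  rows <- list()
  for (seg in segs) {
    a <- seg[1L]; b <- seg[2L]
    len <- b - a + 1L
    for (k in 1:6) {
      if (len < k * thr[[k]]) next
      m <- chars[a:(b - k)] == chars[(a + k):b]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths + k >= k * thr[[k]])
      for (h in hit) {
        run_start <- a + starts[h] - 1L
        run_len <- r$lengths[h] + k              # characters incl. partials
        reps <- run_len %/% k
        if (reps < thr[[k]]) next
        motif <- paste(chars[run_start:(run_start + k - 1L)], collapse = "")
        if (!is_primitive_motif(motif)) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = run_start, end = run_start + reps * k - 1L,
          ext_end = run_start + run_len - 1L,
          class = k, repeats = reps, motif = motif,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Maximal 'N'-free intervals as list of c(start, end).
n_free_segments <- function(chars) {
  ok <- chars != "N"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

# Overlap resolution. Candidates whose complete-copy intervals share at
# least one position are clustered (transitively); each cluster's spanned
# segment (min start .. max ext_end) is re-segmented into the fewest
# adjacent perfect runs meeting thresholds (ties: longest first component,
# then lowest class). If no full-cover segmentation exists the cluster
# falls back to greedy selection: longest run first, then lower class,
# then leftmost; overlapping candidates are dropped.
resolve_overlaps <- function(cand, chars, thr) {
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = integer(0), repeats = integer(0),
                      motif = character(0), stringsAsFactors = FALSE))
  }
  # identical intervals at two classes: keep the lower class
  cand <- cand[order(cand$start, cand$end, cand$class), , drop = FALSE]
  dup <- duplicated(cand[, c("start", "end")])
  cand <- cand[!dup, , drop = FALSE]

  # cluster by interval overlap on complete-copy coordinates
  cl <- integer(nrow(cand))
  cur <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > cur_end) cur <- cur + 1L
    cl[i] <- cur
    cur_end <- max(cur_end, cand$end[i])
  }

  out <- list()
  for (g in split(seq_len(nrow(cand)), cl)) {
    if (length(g) == 1L) {
      out[[length(out) + 1L]] <-
        cand[g, c("start", "end", "class", "repeats", "motif")]
      next
    }
    sub <- cand[g, , drop = FALSE]
    span_a <- min(sub$start)
    for (span_b in unique(c(max(sub$ext_end), max(sub$end)))) {
      seg <- segment_runs(chars[span_a:span_b], thr)
      if (!is.null(seg)) break
    }
    if (!is.null(seg)) {
      seg$start <- seg$start + span_a - 1L
      seg$end <- seg$end + span_a - 1L
      out[[length(out) + 1L]] <-
        seg[, c("start", "end", "class", "repeats", "motif")]
    } else {
      sub <- sub[order(-(sub$end - sub$start + 1L), sub$class, sub$start), ,
                 drop = FALSE]
      taken_s <- integer(0); taken_e <- integer(0)
      for (i in seq_len(nrow(sub))) {
        if (!any(sub$start[i] <= taken_e & sub$end[i] >= taken_s)) {
          taken_s <- c(taken_s, sub$start[i])
          taken_e <- c(taken_e, sub$end[i])
          out[[length(out) + 1L]] <-
            sub[i, c("start", "end", "class", "repeats", "motif")]
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Merge strictly adjacent SSRs into compound SSRs
#'
#' Two or more perfect SSRs of one sample and locus form a compound SSR
#' only when they are directly adjacent with zero interspersed nucleotides
#' (the next component starts exactly one position after the previous one
#' ends). Maximal chains of adjacent SSRs become one compound; everything
#' else stays simple.
#'
#' @param ssrs data.frame from [find_perfect_ssrs()] (one sample/locus per
#'   group; multiple sample/locus combinations are handled independently).
#' @return List with \code{ssrs} (the input plus a \code{compound_id}
#'   column, NA for simple SSRs) and \code{compounds} (one row per
#'   compound: compound_id, sample_id, locus_id, n_components, start, end,
#'   total_length_bp, aln_start, aln_end, notation such as
#'   "(GTAT)3(GT)12").
#' @export
merge_compound <- function(ssrs) {
  ssrs$compound_id <- rep(NA_character_, nrow(ssrs))
  comp_rows <- list()
  if (nrow(ssrs) > 0L) {
    key <- paste(ssrs$sample_id, ssrs$locus_id, sep = "\r")
    for (idx in split(seq_len(nrow(ssrs)), key)) {
      idx <- idx[order(ssrs$start[idx])]
      s <- ssrs$start[idx]; e <- ssrs$end[idx]
      if (length(idx) > 1L && any(s[-1L] <= e[-length(e)])) {
        stop("overlapping SSRs passed to merge_compound", call. = FALSE)
      }
      chain <- cumsum(c(1L, as.integer(s[-1L] != e[-length(e)] + 1L)))
      for (members in split(idx, chain)) {
        if (length(members) < 2L) next
        cid <- sprintf("%s|%s|c%d", ssrs$sample_id[members[1L]],
                       ssrs$locus_id[members[1L]], ssrs$start[members[1L]])
        ssrs$compound_id[members] <- cid
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          compound_id = cid,
          sample_id = ssrs$sample_id[members[1L]],
          locus_id = ssrs$locus_id[members[1L]],
          n_components = length(members),
          start = min(ssrs$start[members]),
          end = max(ssrs$end[members]),
          total_length_bp = sum(ssrs$length_bp[members]),
          aln_start = min(ssrs$aln_start[members]),
          aln_end = max(ssrs$aln_end[members]),
          notation = paste(
            ssr_notation(ssrs$motif[members], ssrs$repeats[members]),
            collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  compounds <- if (length(comp_rows) > 0L) do.call(rbind, comp_rows)
  else data.frame(
    compound_id = character(0), sample_id = character(0),
    locus_id = character(0), n_components = integer(0),
    start = integer(0), end = integer(0), total_length_bp = integer(0),
    aln_start = integer(0), aln_end = integer(0), notation = character(0),
    stringsAsFactors = FALSE
  )
  compounds <- compounds[order(compounds$sample_id, compounds$locus_id,
                               compounds$start, method = "radix"), ,
                         drop = FALSE]
  rownames(compounds) <- NULL
  list(ssrs = ssrs, compounds = compounds)
}

#' Split compound SSRs into their components
#'
#' Returns the component perfect SSRs of one or more compounds unchanged.
#' Category and density tallies count components individually, so this is
#' the identity view of the \code{ssrs} table restricted to a compound.
#'
#' @param merged Result of [merge_compound()].
#' @param compound_id Optional single compound to extract.
#' @return data.frame of component SSR rows.
#' @export
split_compound <- function(merged, compound_id = NULL) {
  ssrs <- merged$ssrs
  if (is.null(compound_id)) {
    ssrs[!is.na(ssrs$compound_id), , drop = FALSE]
  } else {
    ssrs[!is.na(ssrs$compound_id) & ssrs$compound_id == compound_id, ,
         drop = FALSE]
  }
}

#' Remove exon-detected SSRs from a full-dataset detection
#'
#' The exon+flank dataset is mined whole and SSRs also detected in the
#' exon-only dataset are then excluded, leaving the flanking-region set.
#' Matching is a multiset difference on (sample_id, locus_id, motif,
#' repeats): each exon detection removes at most one identical full-dataset
#' detection. When \code{exon_offsets} supplies the exon start position
#' inside the full-dataset degapped fragment (columns sample_id, locus_id,
#' offset), positions are compared too: a full-dataset SSR matches only if
#' \code{start - offset + 1} equals the exon detection's start.
#'
#' @param full data.frame of SSRs mined from the exon+flank dataset.
#' @param exon_detections data.frame of SSRs mined from the exon-only
#'   dataset.
#' @param exon_offsets Optional data.frame enabling positional matching.
#' @return The rows of \code{full} that remain after subtraction.
#' @export
subtract_exon_ssrs <- function(full, exon_detections, exon_offsets = NULL) {
  if (nrow(full) == 0L || nrow(exon_detections) == 0L) return(full)
  key_of <- function(df, start) {
    paste(df$sample_id, df$locus_id, df$motif, df$repeats, start, sep = "\r")
  }
  if (is.null(exon_offsets)) {
    fkey <- key_of(full, "")
    ekey <- key_of(exon_detections, "")
  } else {
    off <- stats::setNames(
      exon_offsets$offset,
      paste(exon_offsets$sample_id, exon_offsets$locus_id, sep = "\r"))
    o <- off[paste(full$sample_id, full$locus_id, sep = "\r")]
    fkey <- key_of(full, full$start - as.integer(o) + 1L)
    ekey <- key_of(exon_detections, exon_detections$start)
  }
  budget <- table(ekey)
  occ <- stats::ave(seq_along(fkey), fkey, FUN = seq_along)
  avail <- budget[fkey]
  avail[is.na(avail)] <- 0L
  keep <- occ > avail
  full[keep, , drop = FALSE]
}

#' Write an SSR table in MISA-style TSV layout
#'
#' Columns mirror MISA's misa-file: ID (sample|locus), SSR nr., SSR type
#' (p1..p6 for simple SSRs of class 1..6, c for compound components), SSR
#' notation, size, start, end - plus aln_start, aln_end and at_edge.
#' Coordinates are 1-based inclusive degapped positions; aln_* are 1-based
#' alignment columns.
#'
#' @param ssrs data.frame with a compound_id column (see [merge_compound()]).
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_ssr_tsv <- function(ssrs, path) {
  ord <- order(ssrs$sample_id, ssrs$locus_id, ssrs$start, method = "radix")
  ssrs <- ssrs[ord, , drop = FALSE]
  id <- paste(ssrs$sample_id, ssrs$locus_id, sep = "|")
  nr <- if (nrow(ssrs) == 0L) integer(0)
  else stats::ave(seq_len(nrow(ssrs)), id, FUN = seq_along)
  if (is.null(ssrs$compound_id)) ssrs$compound_id <- NA_character_
  out <- data.frame(
    ID = id, `SSR nr.` = nr,
    type = ifelse(is.na(ssrs$compound_id), paste0("p", ssrs$class), "c"),
    SSR = ssr_notation(ssrs$motif, ssrs$repeats),
    size = ssrs$length_bp, start = ssrs$start, end = ssrs$end,
    aln_start = ssrs$aln_start, aln_end = ssrs$aln_end,
    at_edge = ssrs$at_edge,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
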