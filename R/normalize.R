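# Compound-SSR normalization: minimal re-segmentation of repetitive
# segments (never the overlap/shared-nucleotide notation), motif-phase
# consensus across samples, and truncation flagging.

# Optimal segmentation of a repetitive segment into adjacent perfect runs.
#
# chars: character vector of one segment (no gaps, no N). Returns NULL if
# the segment cannot be fully covered by perfect runs each meeting its
# class threshold; otherwise a data.frame start/end/class/repeats/motif
# (1-based within the segment) realizing (a) the fewest components,
# (b) among those, the longest earliest component (lexicographically from
# the left), (c) among equal lengths, the lowest motif class.
segment_runs <- function(chars, thr) {
  n <- length(chars)
  if (n == 0L) return(NULL)
  INF <- n + 1L
  best <- c(rep(INF, n), 0L)          # best[i] = min runs covering i..n
  choices <- vector("list", n)        # per i: matrix of (end, class, repeats)
  for (i in n:1) {
    ch <- NULL
    for (k in 1:6) {
      if (i + 2L * k - 1L > n) next
      motif <- chars[i:(i + k - 1L)]
      if (!is_primitive_motif(paste(motif, collapse = ""))) next
      m <- 1L
      while (i + (m + 1L) * k - 1L <= n &&
             all(chars[(i + m * k):(i + (m + 1L) * k - 1L)] == motif)) {
        m <- m + 1L
      }
      if (m < thr[[k]]) next
      for (r in thr[[k]]:m) {
        e <- i + r * k - 1L
        ch <- rbind(ch, c(e, k, r))
        cost <- 1L + best[e + 1L]
        if (cost < best[i]) best[i] <- cost
      }
    }
    choices[i] <- list(ch)   # not [[<-]]: NULL must not drop the element
  }
  if (best[1L] >= INF) return(NULL)
  rows <- list()
  i <- 1L
  while (i <= n) {
    ch <- choices[[i]]
    ok <- ch[1L + best[ch[, 1L] + 1L] == best[i], , drop = FALSE]
    ok <- ok[order(-ok[, 1L], ok[, 2L]), , drop = FALSE]
    e <- ok[1L, 1L]; k <- ok[1L, 2L]; r <- ok[1L, 3L]
    rows[[length(rows) + 1L]] <- data.frame(
      start = i, end = e, class = k, repeats = r,
      motif = paste(chars[i:(i + k - 1L)], collapse = ""),
      stringsAsFactors = FALSE
    )
    i <- e + 1L
  }
  do.call(rbind, rows)
}

#' Normalize a repetitive segment into simple adjacent runs
#'
#' Re-segments a maximal repetitive region into the fewest adjacent
#' perfect runs that each meet their class threshold; among equal-count
#' segmentations the earliest component is made as long as possible. The
#' result never uses overlap/shared-nucleotide notation: the canonical
#' reading of GTATGTATGTAT followed by twelve GT copies is
#' (GTAT)3(GT)12, not (GTAT)2(GTA<T>G)(TG)12.
#'
#' @param raw_sequence_segment Character scalar: the repetitive segment.
#' @param thresholds Minimum repeat counts, see [default_thresholds()].
#' @return A list of class \code{normalized_segment}: \code{components}
#'   (data.frame motif/class/repeats/start/end relative to the segment),
#'   \code{compound} (TRUE when more than one component), and
#'   \code{segment}. If no qualifying segmentation exists, the segment is
#'   returned unchanged with \code{components = NULL} and
#'   \code{compound = NA} (non-SSR).
#' @examples
#' normalize_compound(paste0(strrep("GTAT", 3), strrep("GT", 12)))
#' @export
normalize_compound <- function(raw_sequence_segment,
                               thresholds = default_thresholds()) {
  thresholds <- validate_thresholds(thresholds)
  chars <- strsplit(toupper(raw_sequence_segment), "", fixed = TRUE)[[1L]]
  seg <- segment_runs(chars, thresholds)
  structure(
    list(segment = raw_sequence_segment, components = seg,
         compound = if (is.null(seg)) NA else nrow(seg) > 1L),
    class = "normalized_segment"
  )
}

#' @export
print.normalized_segment <- function(x, ...) {
  if (is.null(x$components)) {
    cat("<non-SSR segment>", x$segment, "\n")
  } else {
    cat(paste(ssr_notation(x$components$motif, x$components$repeats),
              collapse = ""), "\n")
  }
  invisible(x)
}

#' Choose a consensus motif phase across samples
#'
#' When a fragment starts inside an SSR, the motif can be read from
#' different start points (AAG / AGA / GAA). Samples whose SSR is internal
#' (not at a fragment edge) vote for the phase they exhibit; the rotation
#' observed in the most such samples wins, ties going to the
#' lexicographically smallest rotation. Edge-truncated SSRs are then
#' relabeled to the chosen rotation (repeat counts are never changed).
#' If every member is at an edge, all members vote.
#'
#' @param group data.frame with columns sample_id, motif, repeats and a
#'   logical at_edge (or truncated) column; all motifs must be cyclic
#'   rotations of one another.
#' @return A \code{phase_consensus} list: \code{chosen} rotation,
#'   \code{support} (named vector of sample counts per rotation among the
#'   voters), and \code{group} with an added \code{motif_consensus} column.
#' @export
consensus_phase <- function(group) {
  stopifnot(nrow(group) >= 1L)
  edge <- if (!is.null(group$at_edge)) group$at_edge else group$truncated
  if (is.null(edge)) edge <- rep(FALSE, nrow(group))
  rot <- motif_rotations(group$motif[1L])
  if (!all(group$motif %in% rot)) {
    stop("motifs in group are not rotation-equivalent", call. = FALSE)
  }
  voters <- group$motif[!edge]
  if (length(voters) == 0L) voters <- group$motif
  support <- table(factor(voters, levels = sort(rot)))
  top <- names(support)[support == max(support)]
  chosen <- min(top)   # lexicographic tie-break
  group$motif_consensus <- ifelse(edge, chosen, group$motif)
  # internal members keep their own reading unless it already matches:
  # relabeling applies to edge-truncated members only
  structure(
    list(chosen = chosen, support = c(support), group = group),
    class = "phase_consensus"
  )
}

#' Flag SSRs truncated by fragment edges
#'
#' An SSR touching the first or last residue of its (degapped) fragment
#' may be cut by missing data, so an apparent repeat-count polymorphism or
#' phase shift involving it can be an assembly artifact rather than real
#' variation. Sets/overwrites a logical \code{truncated} column.
#'
#' @param ssrs data.frame of SSRs of one sample/locus.
#' @param seq The \code{sample_sequence} they were mined from.
#' @return \code{ssrs} with a \code{truncated} column.
#' @export
flag_truncation <- function(ssrs, seq) {
  stopifnot(inherits(seq, "sample_sequence"))
  n <- nchar(seq$residues)
  ssrs$truncated <- ssrs$start == 1L | ssrs$end == n
  ssrs
}
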