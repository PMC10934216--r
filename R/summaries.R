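# Densities, category/length/motif distributions and per-sample summary
# tables. All tallies operate on component-level SSR rows, so compound
# SSRs contribute each component individually; densities are SSRs per kb,
# rounded half-up to 4 decimals; percentages are rounded half-up to 2.

ROMAN_CLASS <- c("I", "II", "III", "IV", "V", "VI")

#' SSR density (SSRs per kb)
#'
#' \code{(n_ssrs / sequence_bp) * 1000}, rounded half-up to 4 decimals.
#'
#' @param n_ssrs SSR count (vectorized).
#' @param sequence_bp Sequence length in bp; must be positive.
#' @return Density in SSRs per kb.
#' @examples
#' ssr_density(3, 66866)   # 0.0449
#' ssr_density(9, 46126)   # 0.1951
#' @export
ssr_density <- function(n_ssrs, sequence_bp) {
  if (any(sequence_bp <= 0)) {
    stop("sequence_bp must be positive", call. = FALSE)
  }
  round_half_up(n_ssrs / sequence_bp * 1000, 4)
}

#' Per-class SSR counts per sample and overall
#'
#' @param ssrs Component-level SSR rows (compound components individually).
#' @param samples Optional sample order; defaults to first-seen order.
#' @return data.frame: one row per sample with counts I..VI and total,
#'   plus a final "Total" row of per-class sums.
#' @export
category_distribution <- function(ssrs, samples = NULL) {
  if (is.null(samples)) samples <- unique(ssrs$sample_id)
  tab <- table(factor(ssrs$sample_id, levels = samples),
               factor(ssrs$class, levels = 1:6))
  m <- matrix(as.integer(tab), nrow = length(samples),
              dimnames = list(NULL, ROMAN_CLASS))
  out <- data.frame(sample_id = samples, m, total = rowSums(m),
                    stringsAsFactors = FALSE, check.names = FALSE)
  total_row <- data.frame(sample_id = "Total", t(colSums(m)),
                          total = sum(m), stringsAsFactors = FALSE,
                          check.names = FALSE)
  rbind(out, total_row)
}

#' Motif and repeat-number frequencies
#'
#' Counts occurrences of each (motif, repeats) combination and each motif
#' across all repeat numbers. In literal mode motifs are keyed exactly as
#' reported (AG, GA and TC are distinct). With
#' \code{complement_aware = TRUE} each motif is merged with its reverse
#' complement; the key is the lexicographically smaller of the pair and
#' the label shows both (e.g. "AG/CT"). Merging conserves counts.
#'
#' @param ssrs Component-level SSR rows.
#' @param complement_aware Merge reverse-complement motif pairs.
#' @param top_k Number of rows in the \code{top} report.
#' @return List: \code{by_motif_repeats} (motif, repeats, length_bp, n),
#'   \code{by_motif} (motif, n), \code{top} (head of by_motif_repeats by
#'   descending n).
#' @export
motif_frequency <- function(ssrs, complement_aware = FALSE, top_k = 10L) {
  motif <- ssrs$motif
  label <- motif
  if (complement_aware && length(motif) > 0L) {
    rc <- motif_revcomp(motif)
    key <- ifelse(motif <= rc, motif, rc)
    other <- ifelse(motif <= rc, rc, motif)
    label <- ifelse(key == other, key, paste(key, other, sep = "/"))
  }
  df <- data.frame(motif = label, repeats = ssrs$repeats,
                   length_bp = ssrs$length_bp, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(list(by_motif_repeats = cbind(df, n = integer(0)),
                by_motif = data.frame(motif = character(0), n = integer(0)),
                top = cbind(df, n = integer(0))))
  }
  bmr <- stats::aggregate(
    list(n = seq_len(nrow(df))), df[c("motif", "repeats", "length_bp")],
    FUN = length)
  bmr <- bmr[order(-bmr$n, bmr$motif, bmr$repeats), , drop = FALSE]
  bm <- stats::aggregate(list(n = seq_len(nrow(df))), df["motif"],
                         FUN = length)
  bm <- bm[order(-bm$n, bm$motif), , drop = FALSE]
  rownames(bmr) <- rownames(bm) <- NULL
  list(by_motif_repeats = bmr, by_motif = bm,
       top = utils::head(bmr, top_k))
}

#' SSR length histogram
#'
#' Occurrence counts per SSR length (bp), the modal length and its share
#' of all SSRs as a percentage rounded half-up to 2 decimals.
#'
#' @param ssrs Component-level SSR rows.
#' @return List: \code{hist} (length_bp, n), \code{modal_length},
#'   \code{modal_share_pct}, \code{total}.
#' @export
length_distribution <- function(ssrs) {
  if (nrow(ssrs) == 0L) {
    return(list(hist = data.frame(length_bp = integer(0), n = integer(0)),
                modal_length = NA_integer_, modal_share_pct = NA_real_,
                total = 0L))
  }
  tab <- table(ssrs$length_bp)
  hist <- data.frame(length_bp = as.integer(names(tab)),
                     n = as.integer(tab))
  hist <- hist[order(hist$length_bp), , drop = FALSE]
  rownames(hist) <- NULL
  imax <- which.max(hist$n)
  list(hist = hist, modal_length = hist$length_bp[imax],
       modal_share_pct = round_half_up(hist$n[imax] / nrow(ssrs) * 100, 2),
       total = nrow(ssrs))
}

#' Per-sample summary table (per-class counts, compounds, density)
#'
#' One row per sample: SSR counts per motif class I..VI, total simple SSR
#' count (compound components counted individually), number of compound
#' SSRs, sequence length in bp (non-gap residues over all loci) and the
#' SSR density per kb. A footer "Total" row sums the count columns.
#' Samples with sequence but no SSRs get zero counts and density 0;
#' density is NA only when a sample has no sequence at all.
#'
#' @param ssrs Component-level SSR rows.
#' @param stats Per-sample statistics from [sample_stats()].
#' @param compounds Compound table from [merge_compound()] (optional).
#' @return data.frame mirroring the per-sample report layout.
#' @export
build_sample_table <- function(ssrs, stats, compounds = NULL) {
  samples <- stats$sample_id
  cd <- category_distribution(ssrs, samples)
  body <- cd[cd$sample_id != "Total", , drop = FALSE]
  n_compound <- integer(length(samples))
  if (!is.null(compounds) && nrow(compounds) > 0L) {
    tab <- table(factor(compounds$sample_id, levels = samples))
    n_compound <- as.integer(tab)
  }
  bp <- stats$total_bp[match(samples, stats$sample_id)]
  dens <- ifelse(bp > 0, ssr_density(body$total, pmax(bp, 1)), NA_real_)
  out <- data.frame(body[, c("sample_id", ROMAN_CLASS, "total")],
                    n_compound = n_compound, sequence_bp = bp,
                    density = dens, stringsAsFactors = FALSE,
                    check.names = FALSE)
  foot <- data.frame(sample_id = "Total",
                     t(colSums(out[, ROMAN_CLASS, drop = FALSE])),
                     total = sum(out$total),
                     n_compound = sum(out$n_compound),
                     sequence_bp = NA_integer_, density = NA_real_,
                     stringsAsFactors = FALSE, check.names = FALSE)
  rbind(out, foot)
}
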