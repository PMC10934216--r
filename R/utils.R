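# Shared helpers: half-up rounding, motif algebra (primitivity, rotations,
# reverse complement). Motifs are plain upper-case character scalars.

#' Round half away from zero
#'
#' Base R's round() rounds half to even; tables and percentages in this
#' package use the conventional half-up rule instead (0.5 rounds up).
#' A small epsilon absorbs binary floating-point representation error so
#' values that are exactly representable halves still round up.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter motif: "AG" is primitive, "AGAG" is not. Only primitive motifs
#' are ever reported by the miner; a run of "AGAG" is the same run of "AG".
#'
#' @param motif Character scalar over A/C/G/T (case respected).
#' @return TRUE if primitive.
#' @export
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Cyclic rotations of a motif
#'
#' All distinct start phases of a motif: rotations of "AAG" are
#' "AAG", "AGA", "GAA". Rotation equivalence is how the package decides
#' that repeats read from different start points describe the same SSR.
#'
#' @param motif Character scalar.
#' @return Character vector of distinct rotations (includes the input).
#' @export
motif_rotations <- function(motif) {
  k <- nchar(motif)
  if (k <= 1L) return(motif)
  doubled <- paste0(motif, motif)
  unique(vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), ""))
}

# Canonical representative of a rotation class: lexicographically smallest
# rotation. Used as a grouping key only, never as a display label.
rotation_key <- function(motif) {
  vapply(motif, function(m) min(motif_rotations(m)), "", USE.NAMES = FALSE)
}

#' Reverse complement of motifs
#'
#' @param motif Character vector of A/C/G/T motifs.
#' @return Character vector of reverse complements.
#' @export
motif_revcomp <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(motif)))
}

# "(AG)6" style notation for a set of components.
ssr_notation <- function(motif, repeats) {
  if (length(motif) == 0L) return(character(0))
  paste0("(", motif, ")", repeats)
}

# Internal: empty SSR table with the canonical column layout.
empty_ssr_table <- function() {
  data.frame(
    sample_id = character(0), locus_id = character(0),
    motif = character(0), class = integer(0), repeats = integer(0),
    start = integer(0), end = integer(0), length_bp = integer(0),
    aln_start = integer(0), aln_end = integer(0),
    at_edge = logical(0),
    stringsAsFactors = FALSE
  )
}
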