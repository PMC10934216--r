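#' MISA-compatible minimum repeat thresholds
#'
#' Minimum number of complete motif repetitions a perfect SSR must reach to
#' be reported, one value per motif class (1 = mononucleotide ... 6 =
#' hexanucleotide). The defaults are the settings used throughout the
#' package: 12 repeats for mononucleotides, 6 for dinucleotides, 4 for
#' trinucleotides and 3 for tetra-, penta- and hexanucleotides, so the
#' shortest reportable repeat is 12 bp for classes 1-4, 15 bp for class 5
#' and 18 bp for class 6.
#'
#' @return Named integer vector of length 6; names are the motif classes
#'   "1".."6", values the minimum repeat counts.
#' @examples
#' default_thresholds()
#' @export
default_thresholds <- function() {
  c(`1` = 12L, `2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

#' Validate a threshold vector
#'
#' @param thresholds Named vector convertible to integer, with entries for
#'   every motif class 1..6 and all values >= 2.
#' @return The validated thresholds as a named integer vector (invisibly
#'   usable in place of the input).
#' @export
validate_thresholds <- function(thresholds) {
  if (is.null(names(thresholds))) {
    if (length(thresholds) == 6L) names(thresholds) <- as.character(1:6)
    else stop("thresholds must be named by motif class 1..6", call. = FALSE)
  }
  thresholds <- thresholds[as.character(1:6)]
  if (anyNA(thresholds)) {
    stop("thresholds must contain entries for all motif classes 1..6",
         call. = FALSE)
  }
  thresholds <- as.integer(thresholds)
  if (any(thresholds < 2L)) {
    stop("all minimum repeat counts must be >= 2", call. = FALSE)
  }
  names(thresholds) <- as.character(1:6)
  thresholds
}
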