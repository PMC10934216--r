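# Reading per-locus FASTA alignments and the taxonomy table; gap stripping
# with an invertible degapped-position -> alignment-column map; per-sample
# sequence statistics.
#
# Coordinates are 1-based inclusive everywhere: degapped positions index
# residues of one sample's gap-stripped fragment, alignment columns index
# the locus alignment. '-' is the only gap character; 'N' is a residue (it
# is retained by degapping but terminates repeat runs in the miner).

ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Read per-locus FASTA alignments
#'
#' Each file holds one locus: equal-length aligned sequences over
#' A/C/G/T/N/- (case-insensitive; sequences are upper-cased on read). The
#' locus identifier is taken from the file name, pattern "L<digits>"
#' (e.g. \code{L221.fasta} -> "L221"); when the file name carries no such
#' pattern the base name without extension is used.
#'
#' @param paths Character vector of FASTA file paths.
#' @param locus_ids Optional character vector overriding the per-file
#'   locus identifiers (same length as \code{paths}).
#' @return Named list of \code{locus_alignment} objects, each a list with
#'   \code{locus_id}, \code{n_columns} and \code{sequences} (a named
#'   character vector, one aligned sequence per sample, input order kept).
#' @export
read_locus_alignments <- function(paths, locus_ids = NULL) {
  if (length(paths) == 0L) stop("no loci found: empty input", call. = FALSE)
  if (!is.null(locus_ids) && length(locus_ids) != length(paths)) {
    stop("locus_ids must match paths in length", call. = FALSE)
  }
  out <- vector("list", length(paths))
  ids <- character(length(paths))
  for (i in seq_along(paths)) {
    id <- if (!is.null(locus_ids)) locus_ids[[i]] else locus_id_from_path(paths[[i]])
    set <- Biostrings::readBStringSet(paths[[i]])
    if (length(set) == 0L) {
      stop(sprintf("empty alignment file: %s", paths[[i]]), call. = FALSE)
    }
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
    out[[i]] <- new_locus_alignment(id, seqs, paths[[i]])
    ids[[i]] <- id
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated locus id: %s", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  names(out) <- ids
  out
}

locus_id_from_path <- function(path) {
  base <- basename(path)
  m <- regmatches(base, regexpr("L[0-9]+", base))
  if (length(m) == 1L) m else tools::file_path_sans_ext(base)
}

new_locus_alignment <- function(locus_id, sequences, source = NA_character_) {
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "ragged alignment in locus %s: record '%s' has %d columns, expected %d",
      locus_id, names(sequences)[bad], widths[bad], widths[1L]
    ), call. = FALSE)
  }
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  bad <- setdiff(chars, ALLOWED_CHARS)
  if (length(bad) > 0L) {
    stop(sprintf("locus %s: disallowed character(s) %s",
                 locus_id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(locus_id = locus_id, n_columns = widths[[1L]],
         sequences = sequences, source = source),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment %s: %d samples x %d columns>\n",
              x$locus_id, length(x$sequences), x$n_columns))
  invisible(x)
}

#' Strip gaps, keeping an invertible coordinate map
#'
#' Removes '-' from one aligned sequence and records, for every retained
#' residue, the alignment column it came from. \code{colmap[i]} is the
#' 1-based alignment column of the i-th degapped residue, so degapped
#' coordinates from the SSR miner can be lifted back into alignment-column
#' space for cross-sample comparison.
#'
#' @param aligned_sequence Character scalar over A/C/G/T/N/- (upper-cased
#'   internally).
#' @param sample_id,locus_id Labels carried on the result.
#' @return A \code{sample_sequence} object: list with \code{sample_id},
#'   \code{locus_id}, \code{residues} (gap-free string) and \code{colmap}
#'   (integer vector, strictly increasing).
#' @examples
#' s <- degap("A-CG-T", "s1", "L1")
#' s$residues  # "ACGT"
#' s$colmap    # 1 3 4 6
#' @export
degap <- function(aligned_sequence, sample_id = NA_character_,
                  locus_id = NA_character_) {
  stopifnot(is.character(aligned_sequence), length(aligned_sequence) == 1L)
  chars <- strsplit(toupper(aligned_sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% ALLOWED_CHARS))
  if (length(bad) > 0L) {
    stop(sprintf("unknown character '%s' at alignment column %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  keep <- which(chars != "-")
  structure(
    list(sample_id = sample_id, locus_id = locus_id,
         residues = paste(chars[keep], collapse = ""),
         colmap = keep),
    class = "sample_sequence"
  )
}

#' Re-insert gaps (inverse of degap)
#'
#' Reconstructs the aligned sequence from a \code{sample_sequence} and the
#' alignment width; used to verify that degapping is lossless.
#'
#' @param seq A \code{sample_sequence}.
#' @param n_columns Alignment width in columns.
#' @return Character scalar of length \code{n_columns}.
#' @export
regap <- function(seq, n_columns) {
  stopifnot(inherits(seq, "sample_sequence"))
  if (length(seq$colmap) > 0L && max(seq$colmap) > n_columns) {
    stop("colmap exceeds n_columns", call. = FALSE)
  }
  out <- rep("-", n_columns)
  out[seq$colmap] <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  paste(out, collapse = "")
}

#' Read a taxonomy table
#'
#' Tab-separated file with header columns \code{sample_id}, \code{species},
#' \code{genus}, \code{voucher}, \code{sequencing_id} mapping each sample
#' to its species and genus. Species labels ending in " sp." denote samples
#' identified to genus only; the classifier treats each such sample as a
#' distinct species.
#'
#' @param path TSV file path.
#' @return data.frame with the five columns above.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_taxonomy(tab)
}

validate_taxonomy <- function(tab) {
  need <- c("sample_id", "species", "genus")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("taxonomy lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("taxonomy sample_id values must be unique", call. = FALSE)
  }
  if (any(!nzchar(tab$species)) || any(!nzchar(tab$genus))) {
    stop("taxonomy species and genus must be non-empty", call. = FALSE)
  }
  for (col in c("voucher", "sequencing_id")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  }
  tab
}

#' Write a taxonomy table
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample sequence statistics over a dataset
#'
#' For every sample occurring in any locus: the summed number of non-gap
#' residues (\code{total_bp}), the concatenated alignment length over all
#' loci (\code{alignment_total_bp}, identical for every sample), and the
#' missing-data percentage \code{(1 - total_bp/alignment_total_bp) * 100},
#' rounded half-up to 2 decimals. A sample absent from a locus contributes
#' 0 bp for that locus.
#'
#' @param alignments List of \code{locus_alignment} objects.
#' @return data.frame with columns sample_id, total_bp, alignment_total_bp,
#'   missing_pct; samples in first-seen order.
#' @export
sample_stats <- function(alignments) {
  if (length(alignments) == 0L) stop("empty dataset", call. = FALSE)
  aln_total <- sum(vapply(alignments, function(a) a$n_columns, 0L))
  samples <- unique(unlist(lapply(alignments, function(a) names(a$sequences))))
  bp <- stats::setNames(numeric(length(samples)), samples)
  for (aln in alignments) {
    counts <- nchar(gsub("-", "", aln$sequences, fixed = TRUE))
    bp[names(counts)] <- bp[names(counts)] + counts
  }
  data.frame(
    sample_id = samples,
    total_bp = as.integer(bp),
    alignment_total_bp = aln_total,
    missing_pct = round_half_up((1 - bp / aln_total) * 100, 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Degap every sample of every locus
#'
#' Convenience wrapper producing the per-sample \code{sample_sequence}
#' objects the miner consumes. All-gap rows (sample absent from the locus)
#' are dropped.
#'
#' @param alignments List of \code{locus_alignment} objects.
#' @return List of \code{sample_sequence} objects.
#' @export
degap_dataset <- function(alignments) {
  out <- list()
  for (aln in alignments) {
    for (sid in names(aln$sequences)) {
      s <- degap(aln$sequences[[sid]], sid, aln$locus_id)
      if (nchar(s$residues) > 0L) out[[length(out) + 1L]] <- s
    }
  }
  out
}
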