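# Primer-design template extraction and Primer3 Boulder-IO output. Primer
# picking itself is out of process: the package emits/consumes Boulder-IO
# records and never reimplements Primer3's thermodynamics.

#' Extract a primer-design template around one SSR
#'
#' Returns the SSR plus up to \code{flank} bp on each side, clipped to the
#' fragment bounds. A template is ineligible when either clipped flank is
#' shorter than \code{min_flank}: SSRs at or near fragment ends leave no
#' room to place a primer. Eligibility is monotone in \code{min_flank}
#' (lowering it never disqualifies an eligible SSR).
#'
#' @param ssr One SSR row (start/end in degapped coordinates).
#' @param seq The \code{sample_sequence} the SSR was mined from.
#' @param flank Flank length to extract per side (bp).
#' @param min_flank Minimum clipped flank length for eligibility (bp).
#' @return A \code{primer_template} list: template (string),
#'   target_start/target_length (SSR interval inside the template, 1-based),
#'   left_flank/right_flank (clipped lengths), eligible, reason,
#'   sequence_id.
#' @export
extract_template <- function(ssr, seq, flank = 200L, min_flank = 50L) {
  stopifnot(inherits(seq, "sample_sequence"))
  n <- nchar(seq$residues)
  if (ssr$start < 1L || ssr$end > n) {
    stop("SSR outside sequence bounds", call. = FALSE)
  }
  t_start <- max(1L, ssr$start - flank)
  t_end <- min(n, ssr$end + flank)
  left <- ssr$start - t_start
  right <- t_end - ssr$end
  eligible <- left >= min_flank && right >= min_flank
  reason <- if (eligible) NA_character_
  else if (left < min_flank && right < min_flank) "both_flanks_short"
  else if (left < min_flank) "left_flank_short" else "right_flank_short"
  structure(
    list(
      sequence_id = paste(seq$sample_id, seq$locus_id,
                          ssr_notation(ssr$motif, ssr$repeats),
                          ssr$start, sep = "|"),
      template = substr(seq$residues, t_start, t_end),
      target_start = ssr$start - t_start + 1L,
      target_length = ssr$end - ssr$start + 1L,
      left_flank = left, right_flank = right,
      eligible = eligible, reason = reason
    ),
    class = "primer_template"
  )
}

#' Extract templates for a table of SSRs
#'
#' @param ssrs SSR rows (possibly many samples/loci).
#' @param seqs List of \code{sample_sequence} objects covering them.
#' @inheritParams extract_template
#' @return List with \code{templates} (all primer_template objects) and
#'   \code{report} (data.frame: sequence_id, sample_id, locus_id, motif,
#'   repeats, left_flank, right_flank, eligible, reason).
#' @export
extract_templates <- function(ssrs, seqs, flank = 200L, min_flank = 50L) {
  idx <- stats::setNames(
    seq_along(seqs),
    vapply(seqs, function(s) paste(s$sample_id, s$locus_id, sep = "\r"), ""))
  templates <- vector("list", nrow(ssrs))
  rows <- vector("list", nrow(ssrs))
  for (i in seq_len(nrow(ssrs))) {
    key <- paste(ssrs$sample_id[i], ssrs$locus_id[i], sep = "\r")
    s <- seqs[[idx[[key]]]]
    tp <- extract_template(ssrs[i, ], s, flank, min_flank)
    templates[[i]] <- tp
    rows[[i]] <- data.frame(
      sequence_id = tp$sequence_id, sample_id = ssrs$sample_id[i],
      locus_id = ssrs$locus_id[i], motif = ssrs$motif[i],
      repeats = ssrs$repeats[i], left_flank = tp$left_flank,
      right_flank = tp$right_flank, eligible = tp$eligible,
      reason = tp$reason, stringsAsFactors = FALSE
    )
  }
  list(templates = templates, report = do.call(rbind, rows))
}

#' Write Primer3 Boulder-IO input records
#'
#' One record per eligible template: KEY=value lines
#' (SEQUENCE_ID, SEQUENCE_TEMPLATE, SEQUENCE_TARGET=start,length with
#' Primer3's 0-based target start), terminated by a line holding "=".
#' Ineligible templates are skipped.
#'
#' @param templates List of \code{primer_template} objects (or the result
#'   of [extract_templates()]).
#' @param path Output file path.
#' @return Invisibly, the number of records written.
#' @export
write_primer_input <- function(templates, path) {
  if (!is.null(templates$templates)) templates <- templates$templates
  lines <- character(0)
  n <- 0L
  for (tp in templates) {
    if (!isTRUE(tp$eligible)) next
    lines <- c(lines,
               paste0("SEQUENCE_ID=", tp$sequence_id),
               paste0("SEQUENCE_TEMPLATE=", tp$template),
               paste0("SEQUENCE_TARGET=", tp$target_start - 1L, ",",
                      tp$target_length),
               "=")
    n <- n + 1L
  }
  writeLines(lines, path)
  invisible(n)
}

#' Parse a Boulder-IO file
#'
#' @param path Boulder-IO file ("KEY=value" lines, records separated by
#'   "=").
#' @return List of records, each a named character vector.
#' @export
read_boulder <- function(path) {
  lines <- readLines(path)
  records <- list()
  cur <- character(0)
  for (ln in lines) {
    if (ln == "=") {
      records[[length(records) + 1L]] <- cur
      cur <- character(0)
    } else {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 1L) stop(sprintf("malformed Boulder-IO line: %s", ln),
                        call. = FALSE)
      key <- substr(ln, 1L, eq - 1L)
      cur[key] <- substr(ln, eq + 1L, nchar(ln))
    }
  }
  if (length(cur) > 0L) {
    stop("Boulder-IO file does not end with a record terminator",
         call. = FALSE)
  }
  records
}
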