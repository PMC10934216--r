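# End-to-end orchestration: mine -> normalize/compound -> (exon
# subtraction) -> classify -> summarize -> primer templates, both as
# in-memory functions and as config-driven stages writing TSVs. Stage
# outputs are plain TSV so stages can be rerun independently; everything
# is deterministic given inputs and configuration.

#' Mine a whole dataset
#'
#' Degaps every sample of every locus, detects perfect SSRs, flags
#' truncation and merges strictly adjacent runs into compounds.
#'
#' @param alignments Named list of \code{locus_alignment} objects.
#' @param thresholds Minimum repeat counts, see [default_thresholds()].
#' @return List: \code{ssrs} (component-level table with compound_id and
#'   truncated columns), \code{compounds}, \code{seqs} (the degapped
#'   \code{sample_sequence} objects).
#' @export
mine_dataset <- function(alignments, thresholds = default_thresholds()) {
  thresholds <- validate_thresholds(thresholds)
  seqs <- degap_dataset(alignments)
  tabs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- find_perfect_ssrs(seqs[[i]], thresholds)
    tabs[[i]] <- flag_truncation(hits, seqs[[i]])
  }
  ssrs <- do.call(rbind, c(tabs, list(cbind(empty_ssr_table(),
                                            truncated = logical(0)))))
  merged <- merge_compound(ssrs)
  list(ssrs = merged$ssrs, compounds = merged$compounds, seqs = seqs)
}

#' Run the full in-memory analysis
#'
#' Mining, optional exon subtraction, grouping, classification and
#' summaries in one call.
#'
#' @param alignments Named list of \code{locus_alignment} objects (the
#'   dataset to analyze, e.g. exon+flank).
#' @param taxonomy Taxonomy table.
#' @param thresholds Minimum repeat counts.
#' @param exon_alignments Optional exon-only dataset; when given, its
#'   detections are subtracted so classification and summaries describe
#'   the flanking regions.
#' @return List: \code{mining}, \code{exon_mining} (or NULL), \code{ssrs}
#'   (post-subtraction component table), \code{grouping},
#'   \code{classified}, \code{report}, \code{stats}, \code{sample_table}.
#' @export
analyze_dataset <- function(alignments, taxonomy,
                            thresholds = default_thresholds(),
                            exon_alignments = NULL) {
  taxonomy <- validate_taxonomy(taxonomy)
  mining <- mine_dataset(alignments, thresholds)
  exon_mining <- NULL
  ssrs <- mining$ssrs
  if (!is.null(exon_alignments)) {
    exon_mining <- mine_dataset(exon_alignments, thresholds)
    ssrs <- subtract_exon_ssrs(ssrs, exon_mining$ssrs)
  }
  grouping <- group_by_locus(ssrs)
  classified <- classify_groups(grouping, taxonomy)
  report <- classification_report(classified, grouping)
  stats <- sample_stats(alignments)
  # keep taxonomy order where available
  ord <- order(match(stats$sample_id, taxonomy$sample_id))
  stats <- stats[ord, , drop = FALSE]
  sample_table <- build_sample_table(ssrs, stats, mining$compounds)
  list(mining = mining, exon_mining = exon_mining, ssrs = ssrs,
       grouping = grouping, classified = classified, report = report,
       stats = stats, sample_table = sample_table)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with fields: \code{full_dir} (exon+flank FASTA
#' directory), optional \code{exon_dir}, \code{taxonomy} (TSV path),
#' \code{out_dir}, optional \code{thresholds} (map class -> min repeats),
#' \code{complement_aware}, \code{flank}, \code{min_flank}, \code{seed}
#' and simulation fields (\code{n_loci}, \code{locus_length_range},
#' \code{missing_range}, \code{gap_rate}).
#'
#' @param path Config file path.
#' @return Named list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(exon_dir = NULL, complement_aware = FALSE,
                   flank = 200L, min_flank = 50L,
                   thresholds = as.list(default_thresholds()))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$thresholds <- validate_thresholds(unlist(cfg$thresholds))
  cfg
}

pipeline_inputs <- function(config) {
  fasta_paths <- function(dir) {
    p <- list.files(dir, pattern = "\\.(fa|fasta|fas)$", full.names = TRUE)
    if (length(p) == 0L) {
      stop(sprintf("no loci found in %s", dir), call. = FALSE)
    }
    sort(p)
  }
  full <- read_locus_alignments(fasta_paths(config$full_dir))
  exon <- if (!is.null(config$exon_dir)) {
    read_locus_alignments(fasta_paths(config$exon_dir))
  }
  taxonomy <- read_taxonomy(config$taxonomy)
  list(full = full, exon = exon, taxonomy = taxonomy)
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Pipeline stage: mine
#'
#' Mines the exon+flank dataset (and the exon-only dataset when
#' configured), writes per-dataset SSR tables
#' (\code{ssrs_full.tsv}, \code{ssrs_exon.tsv},
#' \code{ssrs_flanking.tsv} after exon subtraction) and the compound
#' table to \code{out_dir}.
#'
#' @param config List from [read_pipeline_config()] (or equivalent).
#' @return Invisibly, the [analyze_dataset()] result.
#' @export
pipeline_mine <- function(config) {
  inp <- pipeline_inputs(config)
  res <- analyze_dataset(inp$full, inp$taxonomy, config$thresholds,
                         exon_alignments = inp$exon)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ssr_tsv(res$mining$ssrs,
                file.path(config$out_dir, "ssrs_full.tsv"))
  if (!is.null(res$exon_mining)) {
    write_ssr_tsv(res$exon_mining$ssrs,
                  file.path(config$out_dir, "ssrs_exon.tsv"))
    write_ssr_tsv(res$ssrs,
                  file.path(config$out_dir, "ssrs_flanking.tsv"))
  }
  write_tsv(res$mining$compounds, config$out_dir, "compounds.tsv")
  invisible(res)
}

#' Pipeline stage: classify
#'
#' Writes group memberships, per-group classifications and category
#' tallies.
#'
#' @inheritParams pipeline_mine
#' @return Invisibly, the analysis result.
#' @export
pipeline_classify <- function(config) {
  inp <- pipeline_inputs(config)
  res <- analyze_dataset(inp$full, inp$taxonomy, config$thresholds,
                         exon_alignments = inp$exon)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$grouping$members, config$out_dir, "group_members.tsv")
  write_tsv(res$classified, config$out_dir, "classifications.tsv")
  write_tsv(res$report$by_class, config$out_dir, "tallies_by_class.tsv")
  write_tsv(res$report$by_category, config$out_dir, "tallies.tsv")
  invisible(res)
}

#' Pipeline stage: summarize
#'
#' Writes the per-sample summary table, missing-data report, motif
#' frequencies (literal and, when configured, complement-aware) and the
#' SSR length histogram.
#'
#' @inheritParams pipeline_mine
#' @return Invisibly, the analysis result.
#' @export
pipeline_summarize <- function(config) {
  inp <- pipeline_inputs(config)
  res <- analyze_dataset(inp$full, inp$taxonomy, config$thresholds,
                         exon_alignments = inp$exon)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$sample_table, config$out_dir, "sample_table.tsv")
  write_tsv(res$stats, config$out_dir, "missing_data.tsv")
  mf <- motif_frequency(res$ssrs, complement_aware =
                          isTRUE(config$complement_aware))
  write_tsv(mf$by_motif_repeats, config$out_dir, "motif_frequency.tsv")
  ld <- length_distribution(res$ssrs)
  write_tsv(ld$hist, config$out_dir, "length_distribution.tsv")
  invisible(res)
}

#' Pipeline stage: primer templates
#'
#' Extracts primer-design templates around each (flanking-region) SSR,
#' writes the eligibility report and the Primer3 Boulder-IO input of the
#' eligible templates.
#'
#' @inheritParams pipeline_mine
#' @return Invisibly, the [extract_templates()] result.
#' @export
pipeline_primers <- function(config) {
  inp <- pipeline_inputs(config)
  res <- analyze_dataset(inp$full, inp$taxonomy, config$thresholds,
                         exon_alignments = inp$exon)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tp <- extract_templates(res$ssrs, res$mining$seqs,
                          flank = config$flank,
                          min_flank = config$min_flank)
  write_tsv(tp$report, config$out_dir, "primer_eligibility.tsv")
  write_primer_input(tp, file.path(config$out_dir, "primer3_input.txt"))
  invisible(tp)
}

#' Pipeline stage: simulate
#'
#' Generates a synthetic dataset under \code{out_dir} using the
#' configuration's simulation fields and seed.
#'
#' @inheritParams pipeline_mine
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
pipeline_simulate <- function(config) {
  args <- list(seed = config$seed)
  for (nm in c("n_loci", "locus_length_range", "missing_range",
               "gap_rate")) {
    if (!is.null(config[[nm]])) args[[nm]] <- config[[nm]]
  }
  if (!is.null(config$taxonomy) && file.exists(config$taxonomy)) {
    args$taxonomy <- read_taxonomy(config$taxonomy)
  }
  cfg <- do.call(simulation_config, args)
  invisible(simulate_dataset(cfg, out_dir = config$out_dir))
}
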