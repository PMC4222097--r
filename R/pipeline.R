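# Pipeline driver: extract -> refine -> merge -> (optional) statistics,
# with per-stage progress logging and preserve-overwrite semantics so an
# initial run's outputs survive later reruns (and hand edits of the merged
# table feed the statistics stage).

#' Pipeline run configuration
#'
#' @param root Study-tree root directory.
#' @param genes Path to the gene list (default
#'   `"<root>/Genes of interest.txt"`).
#' @param center `"mean"` or `"median"` for probe selection and ratios.
#' @param method `"stouffer"` or `"fisher"` p-value combination.
#' @param stouffer_denominator `"sqrt_n"` (canonical) or `"n"`.
#' @param log_mode `"auto"` or `"manual"` (NOLOG folder token).
#' @param auto_log_threshold See [refine_config()].
#' @param run_stats Perform the statistics stage.
#' @param force_overwrite Replace existing outputs instead of preserving
#'   them.
#' @param filters Optional [filter_config()]; when given, the case-study
#'   filters are applied to the merged table before statistics.
#' @param welch Use Welch's t-test.
#' @param bh Add a Benjamini-Hochberg column to the stats summary.
#' @return A `maex_run_config` list.
#' @export
run_config <- function(root,
                       genes = file.path(root, "Genes of interest.txt"),
                       center = c("mean", "median"),
                       method = c("stouffer", "fisher"),
                       stouffer_denominator = c("sqrt_n", "n"),
                       log_mode = c("auto", "manual"),
                       auto_log_threshold = 50,
                       run_stats = TRUE, force_overwrite = FALSE,
                       filters = NULL, welch = FALSE, bh = FALSE) {
  structure(list(root = root, genes = genes,
                 center = match.arg(center), method = match.arg(method),
                 stouffer_denominator = match.arg(stouffer_denominator),
                 log_mode = match.arg(log_mode),
                 auto_log_threshold = auto_log_threshold,
                 run_stats = isTRUE(run_stats),
                 force_overwrite = isTRUE(force_overwrite),
                 filters = filters, welch = isTRUE(welch), bh = isTRUE(bh)),
            class = "maex_run_config")
}

report_dispositions <- function(extracted) {
  rep <- extracted$report
  maex_log("study %d (%s): %d found, %d not in annotation%s, %d annotated but absent from data%s",
           extracted$study_number, extracted$study_name,
           length(rep$found), length(rep$missing_in_annotation),
           if (length(rep$missing_in_annotation) > 0L)
             sprintf(" (%s)", paste(rep$missing_in_annotation, collapse = ", ")) else "",
           length(rep$annotated_but_absent),
           if (length(rep$annotated_but_absent) > 0L)
             sprintf(" (%s)", paste(rep$annotated_but_absent, collapse = ", ")) else "",
           stage = "extract")
}

#' Run the full pipeline on a study tree
#'
#' Stages: scan + extract (per-study gene-disposition report), refine,
#' merge, then (if `run_stats`) per-study t-tests and cross-study p-value
#' combination.  Under the default preserve policy existing `output_*.txt`,
#' `refined_*.txt` and `Merged.txt` files are left untouched; when a
#' `Merged.txt` already exists the statistics stage operates on that file as
#' found on disk, so hand-pruned or re-sorted merged tables are honoured.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `extracted`, `refined`, `merged` (the
#'   table statistics ran on), `stats` (`maex_stats` or `NULL`), and
#'   `merged_path`.
#' @export
run_pipeline <- function(config) {
  overwrite <- if (config$force_overwrite) "force" else "preserve"
  genes <- read_gene_list(config$genes)
  maex_log("gene list: %d identifier(s)", length(genes), stage = "extract")
  folders <- scan_study_folders(config$root)
  maex_log("found %d study folder(s)", length(folders), stage = "extract")

  rconf <- refine_config(center = config$center, log_mode = config$log_mode,
                         auto_log_threshold = config$auto_log_threshold,
                         welch = config$welch)
  n <- length(folders)
  extracted <- vector("list", n)
  refined <- vector("list", n)
  for (i in seq_len(n)) {
    extracted[[i]] <- extract_study(folders[[i]], genes)
    report_dispositions(extracted[[i]])
    persist_extracted(extracted[[i]], config$root, overwrite)
    maex_log("extraction %d%% done", round(100 * i / n), stage = "extract")
  }
  for (i in seq_len(n)) {
    refined[[i]] <- refine_study(extracted[[i]], rconf)
    persist_refined(refined[[i]], config$root, overwrite)
    maex_log("refinement %d%% done", round(100 * i / n), stage = "refine")
  }

  merged <- merge_studies(refined, gene_order = genes)
  merged_path <- file.path(config$root, "Merged.txt")
  if (file.exists(merged_path) && overwrite == "preserve") {
    maex_log("existing Merged.txt preserved; statistics will use it as-is",
             stage = "merge")
    table_for_stats <- load_merged(merged_path)
  } else {
    write_merged(merged, merged_path, overwrite = overwrite)
    table_for_stats <- merged
  }
  maex_log("merging done: %d gene(s) x %d column(s)",
           length(table_for_stats$genes), nrow(table_for_stats$columns),
           stage = "merge")

  if (!is.null(config$filters)) {
    table_for_stats <- apply_filters(table_for_stats, config$filters)
    write_merged(table_for_stats, file.path(config$root, "Merged filtered.txt"),
                 overwrite = "force")
    maex_log("filters applied: %d gene(s) x %d column(s) remain",
             length(table_for_stats$genes), nrow(table_for_stats$columns),
             stage = "merge")
  }

  stats <- NULL
  if (config$run_stats) {
    tests <- study_tests(refined, welch = config$welch)
    stats <- annotate_merged(table_for_stats, tests,
                             stat_config(config$method,
                                         config$stouffer_denominator,
                                         config$bh))
    persist_stats(stats, config$root)
    maex_log("statistics done (%s): %d gene(s) combined", config$method,
             sum(stats$summary$k_used > 0L), stage = "stats")
  }
  invisible(list(extracted = extracted, refined = refined,
                 merged = table_for_stats, stats = stats,
                 merged_path = merged_path))
}

#' Statistics-only run on an existing merged table
#'
#' Recomputes the per-study tests from the study folders in memory (no
#' extraction/refinement outputs are touched), then combines them over
#' exactly the genes and columns present in `Merged.txt` as found on disk —
#' which the user may have sorted or pruned since the initial run.
#'
#' @param config A [run_config()].
#' @return Invisibly, the `maex_stats` object.
#' @export
stats_only <- function(config) {
  merged_path <- file.path(config$root, "Merged.txt")
  if (!file.exists(merged_path)) {
    maex_error(sprintf("no Merged.txt under %s; run the pipeline first",
                       config$root), "maex_io_error")
  }
  table <- load_merged(merged_path)
  if (!is.null(config$filters)) {
    table <- apply_filters(table, config$filters)
  }
  genes <- read_gene_list(config$genes)
  folders <- scan_study_folders(config$root)
  rconf <- refine_config(center = config$center, log_mode = config$log_mode,
                         auto_log_threshold = config$auto_log_threshold,
                         welch = config$welch)
  refined <- lapply(folders, function(f) refine_study(extract_study(f, genes), rconf))
  tests <- study_tests(refined, welch = config$welch)
  stats <- annotate_merged(table, tests,
                           stat_config(config$method,
                                       config$stouffer_denominator, config$bh))
  persist_stats(stats, config$root)
  invisible(stats)
}

#' Validate a study tree without writing anything
#'
#' Scans and parses every study folder and reports the per-study gene
#' dispositions.
#'
#' @param root Study-tree root.
#' @param genes Path to the gene list.
#' @return Invisibly, the list of extraction reports.
#' @export
validate_tree <- function(root,
                          genes = file.path(root, "Genes of interest.txt")) {
  gl <- read_gene_list(genes)
  folders <- scan_study_folders(root)
  reports <- lapply(folders, function(f) {
    ex <- extract_study(f, gl)
    report_dispositions(ex)
    ex$report
  })
  maex_log("tree OK: %d study folder(s), %d gene(s)", length(folders),
           length(gl), stage = "validate")
  invisible(reports)
}
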