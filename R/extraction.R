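# Extraction: map the gene list onto each study's probes and pull matching
# matrix rows, reporting per study which genes were found, which are absent
# from the annotation, and which are annotated but missing from the data.

#' Map genes to probe identifiers via a study annotation
#'
#' Matching is exact and case-sensitive; a gene absent from the annotation
#' maps to an empty probe vector.  Duplicate (gene, probe) annotation rows
#' contribute a single probe.
#'
#' @param genes Character vector of gene identifiers.
#' @param annotation A `maex_annotation` object.
#' @return Named list, one character vector of probe IDs per gene, in
#'   annotation row order.
#' @export
map_genes_to_probes <- function(genes, annotation) {
  recs <- annotation$records
  out <- lapply(genes, function(g) unique(recs$probe_id[recs$gene_id == g]))
  stats::setNames(out, genes)
}

#' Extract expression rows for a gene list from one study
#'
#' Values are copied from the matrix exactly as parsed (no numeric
#' transformation happens at this stage), with sample columns reordered to
#' the design's group order.  The returned report partitions the gene list
#' into three disjoint sets: `found` (at least one annotated probe present
#' in the matrix), `missing_in_annotation`, and `annotated_but_absent`
#' (annotated, but none of its probes has a matrix row).  A gene with some
#' probes present and some absent counts as found.
#'
#' @param folder A `maex_study_folder` from [scan_study_folders()].
#' @param genes Character vector from [read_gene_list()].
#' @return An object of class `maex_extracted`: list with `study_number`,
#'   `study_name`, `nolog_flag`, `design`, `priority_suffixes`, `rows`
#'   (data.frame `gene_id`, `probe_id`), `values` (numeric matrix rows x
#'   samples in design order), `report`, and `source_max` (largest finite
#'   value of the full matrix, used for scale detection downstream).
#' @export
extract_study <- function(folder, genes) {
  design <- folder$design
  expr <- folder$expression
  # cluster sample columns by design group order, preserving listed order
  ord <- unlist(lapply(design$groups, function(g) {
    names(design$sample_to_group)[design$sample_to_group == g]
  }), use.names = FALSE)
  absent <- setdiff(ord, expr$sample_ids)
  if (length(absent) > 0L) {
    maex_error(sprintf(
      "study %d (%s): design sample(s) missing from Data.txt header: %s",
      design$study_number, design$study_name, paste(absent, collapse = ", ")),
      "maex_validation_error")
  }
  mapping <- map_genes_to_probes(genes, folder$annotation)
  n_probes <- lengths(mapping)
  present <- lapply(mapping, function(p) p[p %in% expr$probe_ids])

  missing_in_annotation <- genes[n_probes == 0L]
  found <- genes[n_probes > 0L & lengths(present) > 0L]
  annotated_but_absent <- genes[n_probes > 0L & lengths(present) == 0L]

  gene_col <- rep(found, lengths(present[found]))
  probe_col <- unlist(present[found], use.names = FALSE)
  if (is.null(probe_col)) probe_col <- character(0)
  values <- expr$values[probe_col, ord, drop = FALSE]
  rownames(values) <- NULL

  fin <- expr$values[is.finite(expr$values)]
  structure(list(
    study_number = design$study_number,
    study_name = design$study_name,
    nolog_flag = folder$nolog_flag,
    design = design,
    priority_suffixes = folder$annotation$priority_suffixes,
    rows = data.frame(gene_id = gene_col, probe_id = probe_col,
                      stringsAsFactors = FALSE),
    values = values,
    sample_ids = ord,
    report = list(found = found,
                  missing_in_annotation = missing_in_annotation,
                  annotated_but_absent = annotated_but_absent),
    source_max = if (length(fin) > 0L) max(fin) else NA_real_
  ), class = "maex_extracted")
}

#' Write one study's extracted rows under "Extracted Data"
#'
#' One `output_<study_number>.txt` per study; existing files are preserved
#' unless `overwrite = "force"`.
#'
#' @param extracted A `maex_extracted` object.
#' @param root Study-tree root directory.
#' @param overwrite `"preserve"` or `"force"`.
#' @return The output path, invisibly.
#' @export
persist_extracted <- function(extracted, root,
                              overwrite = c("preserve", "force")) {
  overwrite <- match.arg(overwrite)
  path <- file.path(root, "Extracted Data",
                    sprintf("output_%d.txt", extracted$study_number))
  df <- data.frame(gene_id = extracted$rows$gene_id,
                   probe_id = extracted$rows$probe_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(extracted$values)
  colnames(vals) <- extracted$sample_ids
  write_table(cbind(df, vals), path, overwrite = overwrite)
  invisible(path)
}
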