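# Refinement: resolve each study's expression scale to log2, pick one probe
# per gene by suffix priority with a highest-control-signal tie-break, and
# compute group-versus-control log2 ratios with samples clustered by design.

#' Refinement configuration
#'
#' @param center Central tendency used for probe selection and ratios:
#'   `"mean"` or `"median"`.
#' @param log_mode `"auto"`: decide per study from the data via
#'   [detect_log2()]; `"manual"`: trust the `NOLOG` folder token (folders
#'   without the token are taken as already log2).
#' @param auto_log_threshold Largest value compatible with log2 intensities;
#'   a study whose maximum finite value exceeds it is treated as linear.
#'   Normalized log2 intensities rarely exceed ~16, linear intensities run
#'   into the thousands, so the default of 50 separates the two regimes by
#'   orders of magnitude.
#' @param welch Use Welch's unequal-variance t-test downstream instead of
#'   the default pooled-variance Student t-test.
#' @return A `maex_refine_config` list.
#' @export
refine_config <- function(center = c("mean", "median"),
                          log_mode = c("auto", "manual"),
                          auto_log_threshold = 50,
                          welch = FALSE) {
  center <- match.arg(center)
  log_mode <- match.arg(log_mode)
  if (!is.numeric(auto_log_threshold) || auto_log_threshold <= 1) {
    maex_error("auto_log_threshold must be a number > 1", "maex_config_error")
  }
  structure(list(center = center, log_mode = log_mode,
                 auto_log_threshold = auto_log_threshold,
                 welch = isTRUE(welch)),
            class = "maex_refine_config")
}

#' Decide whether a matrix is already log2-transformed
#'
#' Returns `TRUE` (already log2) iff the maximum finite value is less than
#' or equal to `threshold`.  The decision is logged per study so the user
#' can verify it.
#'
#' @param expression A `maex_expression` object (or anything with a numeric
#'   `values` matrix).
#' @param threshold Decision threshold, see [refine_config()].
#' @return Logical scalar.
#' @export
detect_log2 <- function(expression, threshold = 50) {
  fin <- expression$values[is.finite(expression$values)]
  if (length(fin) == 0L) {
    maex_error("cannot detect scale: matrix has no finite values",
               "maex_validation_error")
  }
  max(fin) <= threshold
}

#' Bring an expression matrix onto the log2 scale
#'
#' Already-log2 input is returned unchanged.  Linear input must be strictly
#' positive; a nonpositive value is a hard error naming the offending cell
#' rather than a silent offset, since normalized intensity matrices should
#' be positive and ad hoc offsets distort ratios.
#'
#' @param expression A `maex_expression` object.
#' @param is_log2 Is the input already on log2 scale?
#' @return The expression object on log2 scale (`scale` set to `"LOG2"`).
#' @export
to_log2 <- function(expression, is_log2) {
  if (isTRUE(is_log2)) {
    expression$scale <- "LOG2"
    return(expression)
  }
  v <- expression$values
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad) > 0L) {
    i <- (bad[1L] - 1L) %% nrow(v) + 1L
    j <- (bad[1L] - 1L) %/% nrow(v) + 1L
    maex_error(sprintf(
      "nonpositive value %g in linear-scale data (probe %s, sample %s); cannot log2-transform",
      v[bad[1L]], rownames(v)[i], colnames(v)[j]), "maex_validation_error")
  }
  expression$values <- log2(v)
  expression$scale <- "LOG2"
  expression
}

#' Rank probes by suffix priority
#'
#' The priority list holds probe-ID suffixes, highest priority first (rank
#' 0).  A probe's rank is the position of the suffix it carries; because one
#' listed suffix may itself end another (`"_s_at"` ends with `"_at"`),
#' candidate suffixes are tested longest first, so `"1001_s_at"` matches
#' `"_s_at"` and not `"_at"`.  A probe matching no listed suffix is excluded
#' (rank `NA`).  With an empty priority list every probe ranks 0.
#'
#' @param probe_ids Character vector of probe identifiers.
#' @param priority_suffixes Character vector of suffixes, best first.
#' @return Integer vector of 0-based ranks; `NA` marks exclusion.
#' @export
probe_priority <- function(probe_ids, priority_suffixes = character(0)) {
  n <- length(probe_ids)
  if (length(priority_suffixes) == 0L) return(rep(0L, n))
  rank <- rep(NA_integer_, n)
  test_order <- order(-nchar(priority_suffixes), seq_along(priority_suffixes))
  for (j in test_order) {
    hit <- is.na(rank) & endsWith(probe_ids, priority_suffixes[j])
    rank[hit] <- j - 1L
  }
  rank
}

#' Select one probe per gene
#'
#' Among candidates of minimal (best) priority rank, the probe with the
#' highest mean/median of the control-group values wins.  Remaining exact
#' ties go to the first candidate in annotation order (logged).  If a
#' non-empty priority list excludes every candidate, `NA` is returned and
#' the caller drops the gene with a warning.
#'
#' @param probe_ids Candidate probe identifiers, in annotation order.
#' @param control_values Numeric matrix, one row per candidate, columns the
#'   control-group samples (missing values allowed).
#' @param priority_suffixes Suffix priority list (may be empty).
#' @param center `"mean"` or `"median"`.
#' @return Index of the selected candidate, or `NA_integer_` if all are
#'   excluded.
#' @export
select_probe <- function(probe_ids, control_values,
                         priority_suffixes = character(0),
                         center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(nrow(control_values) == length(probe_ids))
  rank <- probe_priority(probe_ids, priority_suffixes)
  ok <- which(!is.na(rank))
  if (length(ok) == 0L) return(NA_integer_)
  best_rank <- min(rank[ok])
  cand <- ok[rank[ok] == best_rank]
  if (length(cand) == 1L) return(cand)
  cf <- center_fun(center)
  centers <- apply(control_values[cand, , drop = FALSE], 1L, function(x) {
    if (all(is.na(x))) -Inf else cf(x)
  })
  hit <- cand[which.max(centers)]   # which.max: first maximum = annotation order
  if (sum(centers == max(centers)) > 1L) {
    maex_log("tie on control %s for probes {%s}; keeping first in annotation order (%s)",
             center, paste(probe_ids[cand[centers == max(centers)]], collapse = ", "),
             probe_ids[hit], stage = "refine")
  }
  hit
}

#' Refine one extracted study
#'
#' Resolves the scale to log2 (automatic detection or the `NOLOG` token,
#' per `config$log_mode`), selects one probe per found gene, clusters the
#' samples into their design groups, and computes per-group centers and
#' group-minus-control log2 ratios (i.e. log2 fold changes).  Missing cells
#' are excluded sample-wise; a group with no non-missing value for a gene
#' yields a missing center and ratio.
#'
#' @param extracted A `maex_extracted` object.
#' @param config A [refine_config()].
#' @return An object of class `maex_refined`: `study_number`, `study_name`,
#'   `center`, `groups`, `control_group`, `design_n` (samples per group from
#'   the design), `genes` (data.frame `gene_id`, `probe_id`), `values`
#'   (per-gene named list of per-group log2 sample vectors), `centers` and
#'   `n` (gene x group matrices), `ratios` (gene x non-control-group
#'   matrix), `is_log2` (the scale decision).
#' @export
refine_study <- function(extracted, config = refine_config()) {
  is_log2 <- if (config$log_mode == "auto") {
    if (is.na(extracted$source_max)) {
      maex_error(sprintf("study %d: cannot auto-detect scale of an all-missing matrix",
                         extracted$study_number), "maex_validation_error")
    }
    extracted$source_max <= config$auto_log_threshold
  } else {
    !extracted$nolog_flag
  }
  maex_log("study %d (%s): treated as %s%s -- please check if correct!",
           extracted$study_number, extracted$study_name,
           if (is_log2) "already log2" else "linear (will be log2-transformed)",
           if (config$log_mode == "auto") " [auto-detected]" else " [manual/NOLOG]",
           stage = "refine")

  vals <- extracted$values
  if (!is_log2) {
    fake <- structure(list(values = vals), class = "maex_expression")
    rownames(fake$values) <- extracted$rows$probe_id
    colnames(fake$values) <- extracted$sample_ids
    vals <- to_log2(fake, FALSE)$values
    rownames(vals) <- NULL
  }

  design <- extracted$design
  group_cols <- lapply(design$groups, function(g) {
    which(extracted$sample_ids %in%
            names(design$sample_to_group)[design$sample_to_group == g])
  })
  names(group_cols) <- design$groups
  control <- design$control_group
  cf <- center_fun(config$center)
  safe_center <- function(x) if (all(is.na(x))) NA_real_ else cf(x)

  genes <- unique(extracted$rows$gene_id)
  keep_gene <- character(0); keep_probe <- character(0)
  value_list <- list()
  for (g in genes) {
    idx <- which(extracted$rows$gene_id == g)
    ctrl_mat <- vals[idx, group_cols[[control]], drop = FALSE]
    sel <- select_probe(extracted$rows$probe_id[idx], ctrl_mat,
                        extracted$priority_suffixes, config$center)
    if (is.na(sel)) {
      warning(sprintf("study %d: all probes for gene %s excluded by the priority list; gene dropped",
                      extracted$study_number, g), call. = FALSE)
      next
    }
    row <- vals[idx[sel], ]
    keep_gene <- c(keep_gene, g)
    keep_probe <- c(keep_probe, extracted$rows$probe_id[idx[sel]])
    value_list[[g]] <- lapply(group_cols, function(cols) unname(row[cols]))
  }

  n_gene <- length(keep_gene)
  centers <- matrix(NA_real_, n_gene, length(design$groups),
                    dimnames = list(keep_gene, design$groups))
  n_mat <- matrix(0L, n_gene, length(design$groups),
                  dimnames = list(keep_gene, design$groups))
  for (g in keep_gene) {
    for (grp in design$groups) {
      x <- value_list[[g]][[grp]]
      centers[g, grp] <- safe_center(x)
      n_mat[g, grp] <- sum(!is.na(x))
    }
  }
  non_control <- setdiff(design$groups, control)
  ratios <- centers[, non_control, drop = FALSE] - centers[, control]
  structure(list(
    study_number = extracted$study_number,
    study_name = extracted$study_name,
    center = config$center,
    groups = design$groups,
    control_group = control,
    design_n = stats::setNames(lengths(group_cols), design$groups),
    genes = data.frame(gene_id = keep_gene, probe_id = keep_probe,
                       stringsAsFactors = FALSE),
    values = value_list,
    centers = centers,
    n = n_mat,
    ratios = ratios,
    is_log2 = is_log2
  ), class = "maex_refined")
}

#' Write one study's refined table under "Refined Data"
#'
#' One row per gene: gene, selected probe, then per group its label,
#' non-missing N, center, and ratio versus control (empty for the control
#' group).  Existing files are preserved unless forced.
#'
#' @param refined A `maex_refined` object.
#' @param root Study-tree root directory.
#' @param overwrite `"preserve"` or `"force"`.
#' @return The output path, invisibly.
#' @export
persist_refined <- function(refined, root, overwrite = c("preserve", "force")) {
  overwrite <- match.arg(overwrite)
  path <- file.path(root, "Refined Data",
                    sprintf("refined_%d.txt", refined$study_number))
  df <- refined$genes
  for (k in seq_along(refined$groups)) {
    grp <- refined$groups[k]
    df[[sprintf("group%d", k)]] <- rep(grp, nrow(df))
    df[[sprintf("n%d", k)]] <- refined$n[, grp]
    df[[sprintf("center%d", k)]] <- refined$centers[, grp]
    df[[sprintf("ratio%d", k)]] <-
      if (grp == refined$control_group) NA_real_ else refined$ratios[, grp]
  }
  write_table(df, path, overwrite = overwrite)
  invisible(path)
}
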