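# Synthetic study-tree generator: emits a complete multi-study folder tree
# in the package's plain-text dialect with known injected effects, so every
# pipeline stage can be validated end-to-end without external downloads.

#' Synthetic study-tree configuration
#'
#' Defaults emulate a modest multi-study comparison of diseased versus
#' normal tissue: 6 studies, one disease group versus control, 8 samples per
#' group, unit Gaussian noise on the log2 scale.  Per-gene baselines are
#' drawn uniformly on [6, 12] log2 units (typical normalized intensities);
#' when a gene has several probes, one designated probe is brighter than the
#' rest by `probe_sep` log2 units in every sample, which makes the correct
#' probe-selection answer unambiguous ground truth.
#'
#' @param n_studies Number of studies.
#' @param groups_per_study Groups per study (>= 2; one control plus
#'   `groups_per_study - 1` disease groups).
#' @param samples_per_group Samples per group.
#' @param n_genes Genes in the list.
#' @param probes_per_gene Length-2 integer range; each gene draws its probe
#'   count uniformly from it.
#' @param effect_genes Named numeric: true log2 effect (disease minus
#'   control) injected for those genes in every study; all other genes are
#'   null.
#' @param noise_sd Gaussian noise standard deviation on log2 scale.
#' @param linear_scale_studies Study numbers emitted on linear scale
#'   (values exponentiated, folder tagged `NOLOG`).
#' @param suffix_scheme Probe-ID suffixes, most specific first.
#' @param write_priorities Write the suffix scheme into annotation column 4
#'   (the designated brightest probe then also carries the top-priority
#'   suffix, so priority and brightness agree).
#' @param n_missing_annotation Genes left out of every annotation file.
#' @param n_annotated_absent Genes annotated but absent from every matrix.
#' @param probe_sep Log2 brightness separation between the designated probe
#'   and its siblings.
#' @param baseline_range Range of per-gene log2 baselines.
#' @param scramble_columns Shuffle sample columns in Data.txt so group
#'   members are not contiguous (exercises design-driven clustering).
#' @param seed Integer seed controlling everything.
#' @return A `maex_synth_config` list.
#' @export
synth_config <- function(n_studies = 6L, groups_per_study = 2L,
                         samples_per_group = 8L, n_genes = 40L,
                         probes_per_gene = c(1L, 3L),
                         effect_genes = NULL, noise_sd = 1,
                         linear_scale_studies = integer(0),
                         suffix_scheme = c("_at", "_s_at", "_x_at"),
                         write_priorities = FALSE,
                         n_missing_annotation = 0L,
                         n_annotated_absent = 0L,
                         probe_sep = 2, baseline_range = c(6, 12),
                         scramble_columns = TRUE, seed = 1L) {
  stopifnot(n_studies >= 1L, groups_per_study >= 2L, samples_per_group >= 1L,
            n_genes >= 1L, length(probes_per_gene) == 2L,
            probes_per_gene[1] >= 1L, noise_sd > 0,
            all(linear_scale_studies %in% seq_len(n_studies)),
            n_missing_annotation + n_annotated_absent < n_genes)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  if (!is.null(effect_genes)) {
    stopifnot(!is.null(names(effect_genes)),
              all(names(effect_genes) %in% genes))
  }
  structure(list(n_studies = as.integer(n_studies),
                 groups_per_study = as.integer(groups_per_study),
                 samples_per_group = as.integer(samples_per_group),
                 n_genes = as.integer(n_genes), genes = genes,
                 probes_per_gene = as.integer(probes_per_gene),
                 effect_genes = effect_genes, noise_sd = noise_sd,
                 linear_scale_studies = as.integer(linear_scale_studies),
                 suffix_scheme = suffix_scheme,
                 write_priorities = isTRUE(write_priorities),
                 n_missing_annotation = as.integer(n_missing_annotation),
                 n_annotated_absent = as.integer(n_annotated_absent),
                 probe_sep = probe_sep, baseline_range = baseline_range,
                 scramble_columns = isTRUE(scramble_columns),
                 seed = as.integer(seed)),
            class = "maex_synth_config")
}

#' Generate a synthetic study tree with known ground truth
#'
#' Writes the complete folder layout consumed by [scan_study_folders()]
#' (numbered study folders with `Data.txt`, `Annotation.txt`,
#' `Data Description.txt`, a root `Genes of interest.txt`), plus a
#' `ground_truth.txt` sidecar that the pipeline itself never reads.
#' Expression values are baseline + probe offset + injected effect +
#' Gaussian noise on log2 scale; studies listed in `linear_scale_studies`
#' are exponentiated to linear scale and their folder names carry the
#' `NOLOG` token.  Byte-identical output for identical config (seed
#' included).
#'
#' @param config A [synth_config()].
#' @param root Destination directory (created; must be empty unless
#'   `force`).
#' @param force Allow writing into a non-empty directory.
#' @return Invisibly, the ground-truth data frame (`gene_id`,
#'   `study_number`, `group`, `effect`, `direction`, `best_probe`).
#' @export
generate_tree <- function(config, root, force = FALSE) {
  if (dir.exists(root) &&
      length(list.files(root, all.files = TRUE, no.. = TRUE)) > 0L && !force) {
    maex_error(sprintf("refusing to write into non-empty directory %s (use force)",
                       root), "maex_io_error")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  writeLines(config$genes, file.path(root, "Genes of interest.txt"))

  disease_groups <- if (config$groups_per_study == 2L) "disease" else
    sprintf("disease %d", seq_len(config$groups_per_study - 1L))
  groups <- c("control", disease_groups)
  effects <- stats::setNames(rep(0, config$n_genes), config$genes)
  if (!is.null(config$effect_genes)) {
    effects[names(config$effect_genes)] <- config$effect_genes
  }

  truth <- with_seed(config$seed, {
    # genes hidden from annotation / present in annotation but not in data
    hidden <- character(0); absent <- character(0)
    if (config$n_missing_annotation > 0L) {
      hidden <- utils::tail(config$genes, config$n_missing_annotation)
    }
    if (config$n_annotated_absent > 0L) {
      pool <- setdiff(config$genes, hidden)
      absent <- utils::tail(pool, config$n_annotated_absent)
    }
    rows <- list()
    for (s in seq_len(config$n_studies)) {
      linear <- s %in% config$linear_scale_studies
      folder <- file.path(root, sprintf("%d Study%02d%s", s, s,
                                        if (linear) " NOLOG" else ""))
      dir.create(folder, showWarnings = FALSE)

      sample_ids <- unlist(lapply(groups, function(g) {
        sprintf("s%02d_%s_%d", s, gsub(" ", "", g),
                seq_len(config$samples_per_group))
      }), use.names = FALSE)
      group_of <- rep(groups, each = config$samples_per_group)

      baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                               config$baseline_range[2])
      names(baseline) <- config$genes

      ann_gene <- character(0); ann_probe <- character(0)
      ann_spec <- character(0)
      probe_rows <- list(); probe_ids <- character(0)
      for (gi in seq_along(config$genes)) {
        g <- config$genes[gi]
        if (g %in% hidden) next
        m <- if (config$probes_per_gene[1] == config$probes_per_gene[2]) {
          config$probes_per_gene[1]
        } else {
          sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]), 1L)
        }
        best <- sample.int(m, 1L)
        offsets <- rep(0, m)
        if (m > 1L) offsets[-best] <- -config$probe_sep * seq_len(m - 1L)
        sufs <- if (config$write_priorities) {
          x <- sample(config$suffix_scheme, m, replace = TRUE)
          x[best] <- config$suffix_scheme[1L]
          x
        } else {
          rep(config$suffix_scheme[1L], m)
        }
        ids <- sprintf("%s_p%d%s", g, seq_len(m), sufs)
        ann_gene <- c(ann_gene, rep(g, m))
        ann_probe <- c(ann_probe, ids)
        ann_spec <- c(ann_spec, ifelse(sufs == config$suffix_scheme[1L],
                                       "specific", "cross"))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, study_number = s,
          group = rep(disease_groups, 1L),
          effect = rep(effects[g], length(disease_groups)),
          direction = rep(sign(effects[g]), length(disease_groups)),
          best_probe = ids[best], stringsAsFactors = FALSE)
        if (g %in% absent) next
        eff_of_sample <- ifelse(group_of == "control", 0, effects[g])
        for (j in seq_len(m)) {
          vals <- baseline[g] + offsets[j] + eff_of_sample +
            stats::rnorm(length(sample_ids), 0, config$noise_sd)
          probe_rows[[length(probe_rows) + 1L]] <- vals
          probe_ids <- c(probe_ids, ids[j])
        }
      }
      mat <- do.call(rbind, probe_rows)
      colnames(mat) <- sample_ids
      # the permutation is always drawn so that the RNG stream (and hence
      # every emitted value) is identical whether or not columns scramble
      perm <- sample.int(ncol(mat))
      if (config$scramble_columns) {
        mat <- mat[, perm, drop = FALSE]
      }
      if (linear) mat <- 2^mat

      # Data.txt
      lines <- c(paste(c("ID", colnames(mat)), collapse = "\t"),
                 vapply(seq_len(nrow(mat)), function(i) {
                   paste(c(probe_ids[i], format_num(mat[i, ])), collapse = "\t")
                 }, character(1)))
      writeLines(lines, file.path(folder, "Data.txt"), useBytes = TRUE)

      # Annotation.txt (column 4 carries the priority list row-wise)
      pri <- character(length(ann_gene))
      if (config$write_priorities) {
        k <- seq_along(config$suffix_scheme)
        pri[k] <- config$suffix_scheme
      }
      writeLines(paste(ann_gene, ann_probe, ann_spec, pri, sep = "\t"),
                 file.path(folder, "Annotation.txt"), useBytes = TRUE)

      # Data Description.txt
      desc <- vapply(groups, function(g) {
        label <- if (g == "control") "CONTROL:control" else g
        paste(c(label, sample_ids[group_of == g]), collapse = "\t")
      }, character(1))
      writeLines(desc, file.path(folder, "Data Description.txt"),
                 useBytes = TRUE)
    }
    do.call(rbind, rows)
  })
  truth_file <- truth
  truth_file$seed <- config$seed
  utils::write.table(truth_file, file.path(root, "ground_truth.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' Inject a named defect into a generated tree
#'
#' For negative-path testing: `"comma_decimal"` turns one matrix value's
#' decimal point into a comma; `"duplicate_gene"` appends a duplicate line
#' to the gene list; `"missing_annotation_row"` deletes the last annotation
#' row of study 1; `"unnumbered_folder"` adds a folder without a leading
#' study number.
#'
#' @param root A tree written by [generate_tree()].
#' @param mutation One of the defect names above.
#' @return Invisibly, `NULL`.
#' @export
degrade_tree <- function(root, mutation = c("comma_decimal", "duplicate_gene",
                                            "missing_annotation_row",
                                            "unnumbered_folder")) {
  mutation <- match.arg(mutation)
  study1 <- list.dirs(root, recursive = FALSE)
  study1 <- study1[grepl("^1 ", basename(study1))][1L]
  switch(mutation,
    comma_decimal = {
      path <- file.path(study1, "Data.txt")
      lines <- read_text_lines(path)
      lines[2L] <- sub("(\t[0-9]+)\\.", "\\1,", lines[2L])
      writeLines(lines, path, useBytes = TRUE)
    },
    duplicate_gene = {
      path <- file.path(root, "Genes of interest.txt")
      genes <- read_text_lines(path)
      writeLines(c(genes, genes[1L]), path, useBytes = TRUE)
    },
    missing_annotation_row = {
      path <- file.path(study1, "Annotation.txt")
      lines <- read_text_lines(path)
      last_gene <- strsplit(lines[length(lines)], "\t", fixed = TRUE)[[1L]][1L]
      keep <- !startsWith(lines, paste0(last_gene, "\t"))
      writeLines(lines[keep], path, useBytes = TRUE)
    },
    unnumbered_folder = {
      dir.create(file.path(root, "SubVIs"), showWarnings = FALSE)
      writeLines("helper", file.path(root, "SubVIs", "readme.txt"))
    }
  )
  invisible(NULL)
}
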