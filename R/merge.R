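# Merging: combine refined per-study tables into the single merged
# spreadsheet (one ratio column per study x non-control group, with group
# names, study numbers and sample sizes), plus the case-study filters.

merged_table <- function(genes, columns, ratios) {
  stopifnot(nrow(ratios) == length(genes), ncol(ratios) == nrow(columns))
  dimnames(ratios) <- list(genes, columns$label)
  structure(list(genes = genes, columns = columns, ratios = ratios),
            class = "maex_merged")
}

#' Merge refined studies into one table
#'
#' Columns are ordered by study number then the study's own group order;
#' genes absent from a study get missing cells.  Row order follows
#' `gene_order` (normally the input gene list) restricted to genes found in
#' at least one study; without it, order of first appearance is used.
#'
#' @param refined_list List of `maex_refined` objects.
#' @param gene_order Optional character vector fixing the row order.
#' @return An object of class `maex_merged`: `genes`, `columns` (data.frame
#'   `label`, `study_number`, `study_name`, `group`, `n_group`,
#'   `n_control`), `ratios` (gene x column numeric matrix).
#' @export
merge_studies <- function(refined_list, gene_order = NULL) {
  if (length(refined_list) == 0L) {
    maex_error("no refined studies to merge", "maex_validation_error")
  }
  ord <- order(vapply(refined_list, `[[`, integer(1), "study_number"))
  refined_list <- refined_list[ord]

  cols <- do.call(rbind, lapply(refined_list, function(r) {
    non_control <- setdiff(r$groups, r$control_group)
    data.frame(label = sprintf("S%d|%s", r$study_number, non_control),
               study_number = r$study_number,
               study_name = r$study_name,
               group = non_control,
               n_group = as.integer(r$design_n[non_control]),
               n_control = as.integer(r$design_n[r$control_group]),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(cols$label)) {
    maex_error(sprintf("duplicate (study, group) column(s): %s",
                       paste(unique(cols$label[duplicated(cols$label)]), collapse = ", ")),
               "maex_validation_error")
  }
  seen <- unique(unlist(lapply(refined_list, function(r) r$genes$gene_id),
                        use.names = FALSE))
  genes <- if (is.null(gene_order)) seen else gene_order[gene_order %in% seen]

  ratios <- matrix(NA_real_, length(genes), nrow(cols),
                   dimnames = list(genes, cols$label))
  for (r in refined_list) {
    for (grp in setdiff(r$groups, r$control_group)) {
      lab <- sprintf("S%d|%s", r$study_number, grp)
      common <- intersect(genes, rownames(r$ratios))
      ratios[common, lab] <- r$ratios[common, grp]
    }
  }
  merged_table(genes, cols, ratios)
}

#' @export
print.maex_merged <- function(x, ...) {
  cat(sprintf("maex merged table: %d gene(s) x %d (study, group) column(s), %d stud(ies)\n",
              length(x$genes), nrow(x$columns),
              length(unique(x$columns$study_number))))
  invisible(x)
}

# Merged.txt layout (all tab-separated):
#   Gene  <label...>           header labels
#   #study / #group / #n_group / #n_control / #study_name   metadata rows
#   <gene> <ratio...>          body
#   Gene  <label...>           footer labels (must match the header)
# The first column and the footer label row are the anchors that let a
# hand-sorted or hand-pruned file round-trip back into a valid table.

#' Write a merged table to "Merged.txt" format
#'
#' @param table A `maex_merged` object.
#' @param path Destination file.
#' @param overwrite `"preserve"` or `"force"`.
#' @return Invisibly, `TRUE` if written, `FALSE` if preserved.
#' @export
write_merged <- function(table, path, overwrite = c("preserve", "force")) {
  overwrite <- match.arg(overwrite)
  if (file.exists(path) && overwrite == "preserve") {
    maex_log("existing file preserved (use force to replace): %s", path,
             stage = "merge")
    return(invisible(FALSE))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lab <- paste(c("Gene", table$columns$label), collapse = "\t")
  meta <- c(
    paste(c("#study", table$columns$study_number), collapse = "\t"),
    paste(c("#group", table$columns$group), collapse = "\t"),
    paste(c("#n_group", table$columns$n_group), collapse = "\t"),
    paste(c("#n_control", table$columns$n_control), collapse = "\t"),
    paste(c("#study_name", table$columns$study_name), collapse = "\t")
  )
  body <- vapply(seq_along(table$genes), function(i) {
    paste(c(table$genes[i], format_num(table$ratios[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(lab, meta, body, lab), path, useBytes = TRUE)
  invisible(TRUE)
}

#' Load (a possibly hand-edited) merged table
#'
#' Users may delete gene rows or whole columns and re-sort rows between the
#' merge and statistics stages; the first column (gene IDs) and the footer
#' label row must remain intact, and are validated here.
#'
#' @param path Path to a file written by [write_merged()].
#' @return A `maex_merged` object.
#' @export
load_merged <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    maex_error(sprintf("merged file %s is empty or truncated", path),
               "maex_validation_error")
  }
  split1 <- strsplit(lines, "\t", fixed = TRUE)
  first <- vapply(split1, function(f) f[1L], character(1))
  if (first[1L] != "Gene") {
    maex_error(sprintf(
      "merged file %s: first column altered (header row must start with 'Gene')",
      path), "maex_validation_error")
  }
  header <- split1[[1L]]
  labels <- header[-1L]
  footer_i <- which(first == "Gene")
  footer_i <- footer_i[footer_i > 1L]
  if (length(footer_i) == 0L) {
    maex_error(sprintf(
      "merged file %s: footer label row missing; the column labels at the bottom of the file must remain unchanged",
      path), "maex_validation_error")
  }
  footer_i <- footer_i[length(footer_i)]
  if (!identical(split1[[footer_i]], header)) {
    maex_error(sprintf(
      "merged file %s: footer label row does not match the header labels",
      path), "maex_validation_error")
  }
  meta_i <- which(startsWith(first, "#"))
  meta <- list()
  for (i in meta_i) {
    f <- split1[[i]]
    length(f) <- length(header)
    meta[[sub("^#", "", f[1L])]] <- f[-1L]
  }
  need <- c("study", "group", "n_group", "n_control")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    maex_error(sprintf("merged file %s: missing metadata row(s): %s", path,
                       paste(paste0("#", miss), collapse = ", ")),
               "maex_validation_error")
  }
  body_i <- setdiff(seq_len(footer_i - 1L)[-1L], meta_i)
  genes <- first[body_i]
  if (anyDuplicated(genes)) {
    maex_error(sprintf("merged file %s: duplicated gene row(s): %s", path,
                       paste(unique(genes[duplicated(genes)]), collapse = ", ")),
               "maex_validation_error")
  }
  ratios <- matrix(NA_real_, length(genes), length(labels))
  for (k in seq_along(body_i)) {
    f <- split1[[body_i[k]]]
    if (length(f) > length(header)) {
      maex_error(sprintf("merged file %s: row '%s' has more cells than the header",
                         path, genes[k]), "maex_validation_error")
    }
    length(f) <- length(header)
    v <- trimws(f[-1L])
    v[is.na(v)] <- ""
    num <- suppressWarnings(as.numeric(v))
    if (any(nzchar(v) & is.na(num))) {
      maex_error(sprintf("merged file %s: non-numeric ratio cell in row '%s'",
                         path, genes[k]), "maex_parse_error")
    }
    ratios[k, ] <- num
  }
  sn <- if (is.null(meta$study_name)) rep(NA_character_, length(labels)) else meta$study_name
  cols <- data.frame(label = labels,
                     study_number = as.integer(meta$study),
                     study_name = sn,
                     group = meta$group,
                     n_group = as.integer(meta$n_group),
                     n_control = as.integer(meta$n_control),
                     stringsAsFactors = FALSE)
  merged_table(genes, cols, ratios)
}

#' Filter configuration for the merged table
#'
#' Defaults are the heart-disease case-study values: drop group columns
#' with fewer than 5 samples, genes covered by fewer than 5 studies, and
#' genes on whose direction of regulation fewer than 75% of the
#' contributing studies agree.
#'
#' @param min_group_n Minimum samples per non-control group column.
#' @param min_studies_per_gene Minimum distinct studies with a non-missing
#'   ratio for a gene.
#' @param min_direction_agreement Minimum fraction (in (0, 1]) of
#'   contributing studies sharing the dominant up/down direction.
#' @return A `maex_filter_config` list.
#' @export
filter_config <- function(min_group_n = 5L, min_studies_per_gene = 5L,
                          min_direction_agreement = 0.75) {
  if (min_group_n < 1L || min_studies_per_gene < 1L ||
      min_direction_agreement <= 0 || min_direction_agreement > 1) {
    maex_error("filter thresholds must be positive; agreement in (0, 1]",
               "maex_config_error")
  }
  structure(list(min_group_n = as.integer(min_group_n),
                 min_studies_per_gene = as.integer(min_studies_per_gene),
                 min_direction_agreement = min_direction_agreement),
            class = "maex_filter_config")
}

# A study's direction for a gene is the majority sign over its (remaining)
# group columns; zeros count to neither side, and an exact up/down tie
# yields direction 0 (disagrees with both sides).
study_directions <- function(ratios_row, study_of_col) {
  studies <- unique(study_of_col)
  vapply(studies, function(s) {
    v <- ratios_row[study_of_col == s]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    up <- sum(v > 0); dn <- sum(v < 0)
    if (up > dn) 1 else if (dn > up) -1 else 0
  }, numeric(1))
}

#' Apply the case-study filters to a merged table
#'
#' Three steps, in order: (1) drop columns whose group has fewer than
#' `min_group_n` samples; (2) drop genes with non-missing ratios in fewer
#' than `min_studies_per_gene` distinct studies; (3) drop genes whose
#' dominant direction (majority sign across per-study directions) is shared
#' by less than `min_direction_agreement` of the studies contributing a
#' non-missing cell.
#'
#' @param table A `maex_merged` object.
#' @param config A [filter_config()].
#' @return The filtered `maex_merged` table.
#' @export
apply_filters <- function(table, config = filter_config()) {
  keep_col <- table$columns$n_group >= config$min_group_n
  cols <- table$columns[keep_col, , drop = FALSE]
  ratios <- table$ratios[, keep_col, drop = FALSE]

  if (nrow(cols) == 0L) {
    return(merged_table(character(0), cols, ratios[integer(0), , drop = FALSE]))
  }
  study_of_col <- cols$study_number
  n_studies <- vapply(seq_along(table$genes), function(i) {
    length(unique(study_of_col[!is.na(ratios[i, ])]))
  }, integer(1))
  keep_gene <- n_studies >= config$min_studies_per_gene

  agree <- vapply(seq_along(table$genes), function(i) {
    d <- study_directions(ratios[i, ], study_of_col)
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(0)
    max(sum(d > 0), sum(d < 0)) / length(d)
  }, numeric(1))
  keep_gene <- keep_gene & agree >= config$min_direction_agreement

  merged_table(table$genes[keep_gene], cols,
               ratios[keep_gene, , drop = FALSE])
}
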