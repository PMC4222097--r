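# Readers and writers for the plain-text study-tree dialect.
#
# A study tree looks like:
#   <root>/Genes of interest.txt
#   <root>/<n> <study name>[ NOLOG]/Data.txt            probe x sample matrix
#   <root>/<n> <study name>[ NOLOG]/Annotation.txt       gene -> probe mapping
#   <root>/<n> <study name>[ NOLOG]/Data Description.txt group design
# All files are tab-separated UTF-8 with "." as the decimal separator.

#' Read a gene-of-interest list
#'
#' One identifier per line; blank lines are skipped; order is preserved.
#' Identifiers are compared exactly (case-sensitive), so they must match the
#' per-study annotation spelling (gene symbols or any unique ID such as an
#' Entrez Gene ID).
#'
#' @param path Path to the gene list file.
#' @return Character vector of unique gene identifiers in file order.
#' @export
read_gene_list <- function(path) {
  genes <- trimws(read_text_lines(path))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    maex_error(sprintf("gene list is empty: %s", path), "maex_validation_error")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    maex_error(sprintf("duplicate gene identifier(s) in %s: %s",
                       path, paste(dup, collapse = ", ")),
               "maex_validation_error")
  }
  genes
}

#' Read a per-study probe annotation table
#'
#' Tab-separated with no header: column 1 gene ID, column 2 probe ID,
#' optional column 3 free-text specificity, optional column 4 a probe-ID
#' suffix contributing (in row order) to the priority list used for probe
#' selection (e.g. `"_at"` before `"_s_at"` ranks perfect-match probes above
#' cross-hybridizing ones).
#'
#' @param path Path to the annotation file.
#' @return An object of class `maex_annotation`: list with `records`
#'   (data.frame `gene_id`, `probe_id`, `specificity`) and
#'   `priority_suffixes` (character, highest priority first).
#' @export
read_annotation <- function(path) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  gene <- character(0); probe <- character(0); spec <- character(0)
  suffixes <- character(0)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      maex_error(sprintf(
        "malformed annotation row at line %d of %s: need at least gene and probe columns",
        keep[i], path), "maex_parse_error")
    }
    gene <- c(gene, f[1L])
    probe <- c(probe, f[2L])
    spec <- c(spec, if (length(f) >= 3L && nzchar(f[3L])) f[3L] else NA_character_)
    if (length(f) >= 4L && nzchar(f[4L])) suffixes <- c(suffixes, f[4L])
  }
  if (anyDuplicated(suffixes)) {
    maex_error(sprintf("duplicate priority suffix in column 4 of %s: %s", path,
                       paste(unique(suffixes[duplicated(suffixes)]), collapse = ", ")),
               "maex_validation_error")
  }
  dup <- duplicated(paste(gene, probe, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d duplicated (gene, probe) annotation row(s) in %s collapsed",
                    sum(dup), path), call. = FALSE)
  }
  records <- data.frame(gene_id = gene[!dup], probe_id = probe[!dup],
                        specificity = spec[!dup], stringsAsFactors = FALSE)
  structure(list(records = records, priority_suffixes = suffixes),
            class = "maex_annotation")
}

#' Read a study group design
#'
#' Each non-blank line defines one group: the group label followed by its
#' tab-separated sample column identifiers.  The control group is marked by a
#' leading `CONTROL:` token on its label; if no line is marked, the first
#' listed group is the control.
#'
#' @param path Path to the design file.
#' @return An object of class `maex_design`: list with `study_number`,
#'   `study_name` (filled in by [scan_study_folders()]), `groups` (labels in
#'   file order), `sample_to_group` (named character, sample -> group) and
#'   `control_group`.
#' @export
read_design <- function(path) {
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    maex_error(sprintf("design file is empty: %s", path), "maex_validation_error")
  }
  groups <- character(0)
  control <- NA_character_
  samp <- character(0); samp_grp <- character(0)
  for (i in keep) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    label <- f[1L]
    members <- f[-1L][nzchar(f[-1L])]
    if (startsWith(label, "CONTROL:")) {
      label <- trimws(sub("^CONTROL:", "", label))
      if (!is.na(control)) {
        maex_error(sprintf("more than one CONTROL: group in %s", path),
                   "maex_validation_error")
      }
      control <- label
    }
    if (!nzchar(label)) {
      maex_error(sprintf("empty group label at line %d of %s", i, path),
                 "maex_parse_error")
    }
    if (label %in% groups) {
      maex_error(sprintf("group '%s' listed twice in %s", label, path),
                 "maex_validation_error")
    }
    if (length(members) == 0L) {
      maex_error(sprintf("group '%s' in %s has no samples", label, path),
                 "maex_validation_error")
    }
    clash <- intersect(members, samp)
    if (length(clash) > 0L || anyDuplicated(members)) {
      bad <- unique(c(clash, members[duplicated(members)]))
      maex_error(sprintf("sample(s) assigned to more than one group in %s: %s",
                         path, paste(bad, collapse = ", ")),
                 "maex_validation_error")
    }
    groups <- c(groups, label)
    samp <- c(samp, members)
    samp_grp <- c(samp_grp, rep(label, length(members)))
  }
  if (is.na(control)) control <- groups[1L]
  structure(list(study_number = NA_integer_, study_name = NA_character_,
                 groups = groups,
                 sample_to_group = stats::setNames(samp_grp, samp),
                 control_group = control),
            class = "maex_design")
}

#' Read a normalized expression matrix
#'
#' Tab-separated: header row of sample identifiers (the first header cell is
#' ignored), then one row per probe with the probe ID in column 1.  Empty
#' cells are recorded as missing.  The decimal separator must be `"."`; a
#' `","` anywhere in a value cell is rejected outright, since silently
#' misparsing locale-formatted numbers is the classic failure mode of
#' spreadsheet exports.
#'
#' @param path Path to the matrix file.
#' @return An object of class `maex_expression`: list with `probe_ids`,
#'   `sample_ids`, `values` (numeric matrix probes x samples), `scale`
#'   (`"AUTO"` until resolved) and `nolog_flag`.
#' @export
read_matrix <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    maex_error(sprintf("expression matrix %s needs a header and at least one probe row",
                       path), "maex_parse_error")
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- trimws(header[-1L])
  if (length(sample_ids) == 0L || any(!nzchar(sample_ids))) {
    maex_error(sprintf("matrix %s: header must list one identifier per sample column",
                       path), "maex_parse_error")
  }
  n_col <- length(sample_ids)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  probe_ids <- character(length(body))
  cells <- matrix("", nrow = length(body), ncol = n_col)
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) > n_col + 1L) {
      maex_error(sprintf("matrix %s row %d has %d value cells, expected %d",
                         path, i, length(f) - 1L, n_col), "maex_parse_error")
    }
    length(f) <- n_col + 1L           # pad short rows (trailing empties)
    f[is.na(f)] <- ""
    probe_ids[i] <- trimws(f[1L])
    cells[i, ] <- trimws(f[-1L])
  }
  if (any(!nzchar(probe_ids))) {
    maex_error(sprintf("matrix %s: empty probe identifier at data row %d",
                       path, which(!nzchar(probe_ids))[1L]), "maex_parse_error")
  }
  if (anyDuplicated(probe_ids)) {
    maex_error(sprintf("matrix %s: duplicated probe identifier(s): %s", path,
                       paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")),
               "maex_validation_error")
  }
  comma <- which(grepl(",", cells, fixed = TRUE))
  if (length(comma) > 0L) {
    i <- (comma[1L] - 1L) %% nrow(cells) + 1L
    j <- (comma[1L] - 1L) %/% nrow(cells) + 1L
    maex_error(sprintf(
      "matrix %s: value '%s' (probe %s, sample %s) contains ','; use '.' as the decimal separator",
      path, cells[i, j], probe_ids[i], sample_ids[j]), "maex_decimal_error")
  }
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(nzchar(cells) & is.na(vals))
  if (length(bad) > 0L) {
    i <- (bad[1L] - 1L) %% nrow(cells) + 1L
    j <- (bad[1L] - 1L) %/% nrow(cells) + 1L
    maex_error(sprintf("matrix %s: non-numeric value '%s' at probe %s, sample %s",
                       path, cells[i, j], probe_ids[i], sample_ids[j]),
               "maex_parse_error")
  }
  values <- matrix(vals, nrow = nrow(cells), ncol = n_col,
                   dimnames = list(probe_ids, sample_ids))
  structure(list(probe_ids = probe_ids, sample_ids = sample_ids,
                 values = values, scale = "AUTO", nolog_flag = FALSE),
            class = "maex_expression")
}

# Folder names start with the study number followed by a space; "NOLOG" as a
# whitespace-delimited token (case-sensitive) marks linear-scale data.
parse_folder_name <- function(name) {
  m <- regmatches(name, regexec("^([0-9]+) (.+)$", name))[[1L]]
  if (length(m) == 0L) return(NULL)
  tokens <- strsplit(m[3L], " ", fixed = TRUE)[[1L]]
  nolog <- "NOLOG" %in% tokens
  list(study_number = as.integer(m[2L]),
       study_name = paste(tokens[tokens != "NOLOG"], collapse = " "),
       nolog_flag = nolog)
}

#' Scan a root directory for numbered study folders
#'
#' Folders whose name does not begin with an integer followed by a space
#' (e.g. a `SubVIs` helper folder) are skipped with a warning, as are the
#' pipeline's own output folders.  Studies are returned sorted by study
#' number regardless of filesystem order.
#'
#' @param root Root directory of the study tree.
#' @param read_data Read the three per-study files (default) or only parse
#'   folder names.
#' @return List of `maex_study_folder` objects sorted by study number, each
#'   with `path`, `study_number`, `study_name`, `nolog_flag`, `design`,
#'   `annotation`, `expression`.
#' @export
scan_study_folders <- function(root, read_data = TRUE) {
  if (!dir.exists(root)) {
    maex_error(sprintf("study root not found: %s", root), "maex_io_error")
  }
  output_dirs <- c("Extracted Data", "Refined Data")
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  folders <- list()
  for (d in dirs) {
    nm <- basename(d)
    if (nm %in% output_dirs) next
    info <- parse_folder_name(nm)
    if (is.null(info)) {
      warning(sprintf("skipping folder without a leading study number: %s", nm),
              call. = FALSE)
      next
    }
    folder <- structure(c(list(path = d), info,
                          list(design = NULL, annotation = NULL,
                               expression = NULL)),
                        class = "maex_study_folder")
    if (read_data) {
      design <- read_design(file.path(d, "Data Description.txt"))
      design$study_number <- info$study_number
      design$study_name <- info$study_name
      expression <- read_matrix(file.path(d, "Data.txt"))
      expression$nolog_flag <- info$nolog_flag
      folder$design <- design
      folder$annotation <- read_annotation(file.path(d, "Annotation.txt"))
      folder$expression <- expression
    }
    folders[[length(folders) + 1L]] <- folder
  }
  if (length(folders) == 0L) {
    maex_error(sprintf("no numbered study folders under %s", root),
               "maex_validation_error")
  }
  nums <- vapply(folders, `[[`, integer(1), "study_number")
  if (anyDuplicated(nums)) {
    maex_error(sprintf("duplicated study number(s) under %s: %s", root,
                       paste(unique(nums[duplicated(nums)]), collapse = ", ")),
               "maex_validation_error")
  }
  folders[order(nums)]
}

#' Write a tab-separated table with a preserve/force overwrite policy
#'
#' Outputs already on disk are never clobbered under the default `"preserve"`
#' policy, so incremental reruns (e.g. after adding one study) keep earlier
#' results; a skip is logged instead.
#'
#' @param x Data frame (or matrix) to write.
#' @param path Destination file.
#' @param overwrite `"preserve"` (default) or `"force"`.
#' @param col.names Write the header row.
#' @return Invisibly, `TRUE` if the file was written, `FALSE` if preserved.
#' @export
write_table <- function(x, path, overwrite = c("preserve", "force"),
                        col.names = TRUE) {
  overwrite <- match.arg(overwrite)
  if (file.exists(path) && overwrite == "preserve") {
    maex_log("existing file preserved (use force to replace): %s", path,
             stage = "write")
    return(invisible(FALSE))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = col.names,
                     fileEncoding = "UTF-8")
  invisible(TRUE)
}
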