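# Shared fixture builders and independent oracles, all built in code.

# --- tiny hand-written study folder ------------------------------------

write_study_folder <- function(root, number = 1L, name = "StudyA",
                               nolog = FALSE,
                               matrix_lines = NULL, annotation_lines = NULL,
                               design_lines = NULL) {
  folder <- file.path(root, sprintf("%d %s%s", number, name,
                                    if (nolog) " NOLOG" else ""))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(matrix_lines)) {
    writeLines(matrix_lines, file.path(folder, "Data.txt"))
  }
  if (!is.null(annotation_lines)) {
    writeLines(annotation_lines, file.path(folder, "Annotation.txt"))
  }
  if (!is.null(design_lines)) {
    writeLines(design_lines, file.path(folder, "Data Description.txt"))
  }
  folder
}

# a minimal 2-gene, 3-probe study: GA has two probes, GB one; control n=3,
# disease n=3
basic_study_lines <- function() {
  list(
    matrix = c("ID\tc1\tc2\tc3\td1\td2\td3",
               "pA1_at\t8\t8.2\t7.8\t6\t6.2\t5.8",
               "pA2_s_at\t9\t9.1\t8.9\t7\t7.1\t6.9",
               "pB1_at\t5\t5.1\t4.9\t7\t7.1\t6.9"),
    annotation = c("GA\tpA1_at", "GA\tpA2_s_at", "GB\tpB1_at"),
    design = c("CONTROL:control\tc1\tc2\tc3", "disease\td1\td2\td3")
  )
}

make_basic_tree <- function(root = withr_tempdir()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("GA", "GB", "GC"), file.path(root, "Genes of interest.txt"))
  l <- basic_study_lines()
  write_study_folder(root, 1L, "StudyA", matrix_lines = l$matrix,
                     annotation_lines = l$annotation, design_lines = l$design)
  root
}

withr_tempdir <- function() {
  d <- tempfile("maextest")
  dir.create(d)
  d
}

expression_from_matrix <- function(m) {
  structure(list(probe_ids = rownames(m), sample_ids = colnames(m),
                 values = m, scale = "AUTO", nolog_flag = FALSE),
            class = "maex_expression")
}

# --- independent oracles ------------------------------------------------

# Exact chi-square upper tail at even dof 2k: the Poisson partial sum
# exp(-x/2) * sum_{j<k} (x/2)^j / j!  (closed form, no pchisq involved).
chisq_sf_even_oracle <- function(x, k) {
  h <- x / 2
  terms <- vapply(0:(k - 1L), function(j) exp(-h + j * log(h) - lgamma(j + 1)),
                  numeric(1))
  sum(terms)
}

# Brute-force suffix matcher: for one probe, enumerate every listed suffix
# that the ID ends with and keep the longest (ties: first listed).
probe_priority_brute <- function(probe_id, suffixes) {
  hits <- which(vapply(suffixes, function(s) {
    nchar(probe_id) >= nchar(s) &&
      substring(probe_id, nchar(probe_id) - nchar(s) + 1L) == s
  }, logical(1)))
  if (length(hits) == 0L) return(NA_integer_)
  best <- hits[order(-nchar(suffixes[hits]), hits)][1L]
  best - 1L
}

# Brute-force re-implementation of the merged-table filters, written
# independently as explicit loops over a plain ratio matrix.
filters_brute <- function(ratios, study_of_col, n_group, min_n, min_studies,
                          min_agree) {
  keep_col <- which(n_group >= min_n)
  keep_gene <- logical(nrow(ratios))
  for (i in seq_len(nrow(ratios))) {
    contributing <- c()
    dirs <- c()
    for (s in unique(study_of_col[keep_col])) {
      v <- ratios[i, keep_col[study_of_col[keep_col] == s]]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      contributing <- c(contributing, s)
      up <- sum(v > 0); dn <- sum(v < 0)
      dirs <- c(dirs, if (up > dn) 1 else if (dn > up) -1 else 0)
    }
    if (length(contributing) < min_studies) next
    frac <- max(sum(dirs == 1), sum(dirs == -1)) / length(dirs)
    keep_gene[i] <- frac >= min_agree
  }
  list(cols = keep_col, genes = which(keep_gene))
}

# Simulated two-group meta experiment operating directly on random normal
# draws through the package's t-test and both combination routes.
simulate_meta <- function(n_genes, n_studies, n_per_group, sd = 1, delta = 0) {
  p_s <- p_f <- sgn <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    p1 <- numeric(n_studies); d1 <- numeric(n_studies)
    for (s in seq_len(n_studies)) {
      tt <- one_tailed_t(rnorm(n_per_group, delta, sd),
                         rnorm(n_per_group, 0, sd))
      p1[s] <- tt$p_one; d1[s] <- tt$direction
    }
    ms <- combine_tests(p1, d1, "stouffer")
    mf <- combine_tests(p1, d1, "fisher")
    p_s[g] <- ms$p_combined
    p_f[g] <- mf$p_combined
    sgn[g] <- ms$direction_consensus
  }
  list(stouffer = p_s, fisher = p_f, sign = sgn)
}

# One-shot scipy oracle: df has columns fun ('norm_isf', 'norm_sf',
# 'chi2_sf'), x, and k (chi-square dof parameter; ignored otherwise).
# Returns the numeric results computed by an independent high-precision
# implementation via the system python.
scipy_oracle <- function(df) {
  stopifnot(all(df$fun %in% c("norm_isf", "norm_sf", "chi2_sf")))
  infile <- tempfile(fileext = ".tsv"); outfile <- tempfile(fileext = ".tsv")
  utils::write.table(format(df, digits = 17), infile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from scipy.stats import norm, chi2",
    "rows = [l.rstrip('\\n').split('\\t') for l in open(sys.argv[1])][1:]",
    "out = []",
    "for fun, x, k in rows:",
    "    x = float(x)",
    "    if fun == 'norm_isf':   out.append(norm.isf(x))",
    "    elif fun == 'norm_sf':  out.append(norm.sf(x))",
    "    else:                   out.append(chi2.sf(x, 2 * int(k)))",
    "open(sys.argv[2], 'w').write('\\n'.join(repr(float(v)) for v in out) + '\\n')"
  ), script)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  as.numeric(readLines(outfile))
}
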