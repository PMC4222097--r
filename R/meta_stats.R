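# Meta-statistics: per-(study, group) one-tailed two-sample t-tests against
# the control group, combined across studies per gene by the signed Stouffer
# Z-transform or by Fisher's chi-square method.

# p-values of exactly 0 or 1 break both transforms; clamp to representable
# bounds and warn.
clamp_p <- function(p) {
  lo <- 1e-300
  hi <- 1 - 1e-16
  if (any(p < lo | p > hi)) {
    warning("p-value(s) at 0 or 1 clamped to machine-representable bounds",
            call. = FALSE)
  }
  pmin(pmax(p, lo), hi)
}

#' One-tailed two-sample Student t-test
#'
#' Pooled-variance two-sample t-test (Welch optional) returning the
#' single-tail probability in the observed direction, i.e. half the
#' two-sided p.  Missing values are dropped sample-wise; fewer than two
#' usable values on either side makes the comparison untestable (it is
#' excluded from combination).  Direction is the sign of the group-minus-
#' control mean difference and is 0 only when the means are exactly equal.
#'
#' @param group_values Numeric vector, the non-control group's log2 values.
#' @param control_values Numeric vector, the control group's log2 values.
#' @param welch Use Welch's unequal-variance test instead of pooled variance.
#' @return List with `p_one`, `direction`, `t_stat`, `df`, `testable`.
#' @export
one_tailed_t <- function(group_values, control_values, welch = FALSE) {
  x <- group_values[!is.na(group_values)]
  y <- control_values[!is.na(control_values)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    return(list(p_one = NA_real_, direction = NA_real_, t_stat = NA_real_,
                df = NA_real_, testable = FALSE))
  }
  mx <- mean(x); my <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  delta <- mx - my
  direction <- sign(delta)
  if (delta == 0) {
    t_stat <- 0
  } else if (se == 0) {
    t_stat <- direction * Inf
  } else {
    t_stat <- delta / se
  }
  p_one <- stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(p_one = p_one, direction = direction, t_stat = t_stat, df = df,
       testable = TRUE)
}

#' Combine one-tailed p-values by the signed Stouffer Z-transform
#'
#' Each one-tailed p is transformed to `Z_i = qnorm(1 - p_i)` and signed by
#' its direction of regulation, so consistent effects accumulate and
#' opposing effects cancel.  The combined score is `Z_s = sum(Z_i) /
#' sqrt(N)` (the canonical unweighted statistic, standard normal under the
#' null); `denominator = "n"` divides by `N` instead.  The combined
#' two-sided p is `2 * (1 - pnorm(|Z_s|))`.
#'
#' @param p_one Numeric vector of one-tailed p-values.
#' @param direction Numeric vector of signs (+1 up, -1 down, 0 no change).
#' @param denominator `"sqrt_n"` (default) or `"n"`.
#' @return An object of class `maex_meta`: `method`, `z_scores`,
#'   `z_combined`, `n_scores`, `p_combined`, `direction_consensus`.
#' @export
stouffer_combine <- function(p_one, direction,
                             denominator = c("sqrt_n", "n")) {
  denominator <- match.arg(denominator)
  if (length(p_one) < 1L || length(p_one) != length(direction)) {
    maex_error("need >= 1 p-value with one direction each", "maex_config_error")
  }
  p <- clamp_p(p_one)
  z <- stats::qnorm(p, lower.tail = FALSE) * direction
  n <- length(z)
  z_s <- sum(z) / if (denominator == "sqrt_n") sqrt(n) else n
  p_s <- 2 * stats::pnorm(abs(z_s), lower.tail = FALSE)
  structure(list(method = "stouffer", z_scores = z, z_combined = z_s,
                 n_scores = n, p_combined = max(p_s, 1e-300),
                 direction_consensus = sign(z_s)),
            class = "maex_meta")
}

#' Combine one-tailed p-values by Fisher's method
#'
#' `chi2 = -2 * sum(log(p_i))` referred to a chi-square distribution with
#' `2k` degrees of freedom, `k` the number of p-values.  Fisher's statistic
#' is sign-blind; the reported consensus direction is the majority sign of
#' the per-study directions (0 on an exact tie).
#'
#' @param p_one Numeric vector of one-tailed p-values.
#' @param direction Optional numeric vector of signs for the consensus.
#' @return An object of class `maex_meta`: `method`, `chi2`, `dof`, `k`,
#'   `p_combined`, `direction_consensus`.
#' @export
fisher_combine <- function(p_one, direction = NULL) {
  if (length(p_one) < 1L) {
    maex_error("need >= 1 p-value", "maex_config_error")
  }
  p <- clamp_p(p_one)
  k <- length(p)
  chi2 <- -2 * sum(log(p))
  p_c <- stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE)
  consensus <- if (is.null(direction)) {
    NA_real_
  } else {
    up <- sum(direction > 0); dn <- sum(direction < 0)
    if (up > dn) 1 else if (dn > up) -1 else 0
  }
  structure(list(method = "fisher", chi2 = chi2, dof = 2L * k, k = k,
                 p_combined = max(p_c, 1e-300),
                 direction_consensus = consensus),
            class = "maex_meta")
}

#' @export
print.maex_meta <- function(x, ...) {
  if (x$method == "stouffer") {
    cat(sprintf("Stouffer combination: Z = %.4f over %d score(s), two-sided p = %.4g, sign %+d\n",
                x$z_combined, x$n_scores, x$p_combined, x$direction_consensus))
  } else {
    cat(sprintf("Fisher combination: chi2 = %.4f (df %d), p = %.4g, sign %s\n",
                x$chi2, x$dof, x$p_combined,
                if (is.na(x$direction_consensus)) "NA"
                else sprintf("%+d", x$direction_consensus)))
  }
  invisible(x)
}

#' Per-(study, group) t-tests for all refined studies
#'
#' Runs [one_tailed_t()] for every gene and non-control group of every
#' refined study.
#'
#' @param refined_list List of `maex_refined` objects.
#' @param welch Use Welch's t-test.
#' @return Data frame with `gene_id`, `study_number`, `group`, `label`,
#'   `p_one`, `direction`, `t_stat`, `df`, `testable`.
#' @export
study_tests <- function(refined_list, welch = FALSE) {
  out <- list()
  for (r in refined_list) {
    non_control <- setdiff(r$groups, r$control_group)
    for (g in r$genes$gene_id) {
      ctrl <- r$values[[g]][[r$control_group]]
      for (grp in non_control) {
        tt <- one_tailed_t(r$values[[g]][[grp]], ctrl, welch = welch)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, study_number = r$study_number, group = grp,
          label = sprintf("S%d|%s", r$study_number, grp),
          p_one = tt$p_one, direction = tt$direction, t_stat = tt$t_stat,
          df = tt$df, testable = tt$testable, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), study_number = integer(0),
                      group = character(0), label = character(0),
                      p_one = numeric(0), direction = numeric(0),
                      t_stat = numeric(0), df = numeric(0),
                      testable = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Combine one study-level test set per gene
#'
#' The combination rule the pipeline applies to a gene's per-(study, group)
#' one-tailed t-test results.  Stouffer receives the one-tailed p-values
#' with their signs (the canonical signed Z-transform, standard normal under
#' the null).  Fisher is sign-blind, so it receives the two-sided p-values
#' `min(1, 2 * p_one)`: feeding a direction-informed one-tailed p (uniform
#' on (0, 0.5] under the null) into Fisher's chi-square sum double-counts
#' the observed direction and inflates the false-positive rate several-fold,
#' whereas the two-sided p is uniform on (0, 1) and keeps the chi-square
#' reference distribution exact.
#'
#' @param p_one One-tailed p-values.
#' @param direction Signs of the per-study effects.
#' @param method `"stouffer"` or `"fisher"`.
#' @param stouffer_denominator `"sqrt_n"` or `"n"`.
#' @return A `maex_meta` object.
#' @export
combine_tests <- function(p_one, direction, method = c("stouffer", "fisher"),
                          stouffer_denominator = c("sqrt_n", "n")) {
  method <- match.arg(method)
  if (method == "stouffer") {
    stouffer_combine(p_one, direction, match.arg(stouffer_denominator))
  } else {
    fisher_combine(pmin(1, 2 * p_one), direction)
  }
}

#' Statistics configuration
#'
#' @param method `"stouffer"` or `"fisher"`.
#' @param stouffer_denominator `"sqrt_n"` (canonical) or `"n"`.
#' @param bh Add a Benjamini-Hochberg adjusted column to the summary
#'   (off by default; the combined p-values are reported raw).
#' @return A `maex_stat_config` list.
#' @export
stat_config <- function(method = c("stouffer", "fisher"),
                        stouffer_denominator = c("sqrt_n", "n"),
                        bh = FALSE) {
  structure(list(method = match.arg(method),
                 stouffer_denominator = match.arg(stouffer_denominator),
                 bh = isTRUE(bh)),
            class = "maex_stat_config")
}

#' Combine per-study tests per gene and annotate a merged table
#'
#' Only tests whose (study, group) column is still present in `table` (which
#' may have been hand-edited between runs) and whose gene row survives are
#' combined; untestable comparisons are skipped with a log note.  Genes with
#' no testable comparison get a missing combined p.
#'
#' @param table A `maex_merged` object (possibly reloaded/edited).
#' @param tests Data frame from [study_tests()].
#' @param config A [stat_config()].
#' @return An object of class `maex_stats`: the input `table`, `p_matrix`
#'   (gene x column one-tailed p-values), and `summary` (data.frame
#'   `gene_id`, `method`, `statistic`, `dof_or_n`, `k_used`,
#'   `n_studies_used`, `p_combined`, `sign`, optionally `p_bh`).
#' @export
annotate_merged <- function(table, tests, config = stat_config()) {
  tests <- tests[tests$label %in% table$columns$label &
                   tests$gene_id %in% table$genes, , drop = FALSE]
  n_skip <- sum(!tests$testable)
  if (n_skip > 0L) {
    maex_log("%d comparison(s) untestable (fewer than 2 values per side); excluded from combination",
             n_skip, stage = "stats")
  }
  tests <- tests[tests$testable, , drop = FALSE]

  p_matrix <- matrix(NA_real_, length(table$genes), nrow(table$columns),
                     dimnames = list(table$genes, table$columns$label))
  if (nrow(tests) > 0L) {
    p_matrix[cbind(match(tests$gene_id, table$genes),
                   match(tests$label, table$columns$label))] <- tests$p_one
  }

  rows <- lapply(table$genes, function(g) {
    tg <- tests[tests$gene_id == g, , drop = FALSE]
    if (nrow(tg) == 0L) {
      return(data.frame(gene_id = g, method = config$method,
                        statistic = NA_real_, dof_or_n = NA_real_,
                        k_used = 0L, n_studies_used = 0L,
                        p_combined = NA_real_, sign = NA_real_,
                        stringsAsFactors = FALSE))
    }
    meta <- combine_tests(tg$p_one, tg$direction, config$method,
                          config$stouffer_denominator)
    data.frame(gene_id = g, method = config$method,
               statistic = if (config$method == "stouffer") meta$z_combined else meta$chi2,
               dof_or_n = if (config$method == "stouffer") meta$n_scores else meta$dof,
               k_used = nrow(tg),
               n_studies_used = length(unique(tg$study_number)),
               p_combined = meta$p_combined,
               sign = meta$direction_consensus,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  if (isTRUE(config$bh)) {
    summary$p_bh <- stats::p.adjust(summary$p_combined, method = "BH")
  }
  structure(list(table = table, p_matrix = p_matrix, summary = summary),
            class = "maex_stats")
}

#' @export
print.maex_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("maex statistics (%s): %d gene(s); %d with combined p < 0.05\n",
              s$method[1], nrow(s), sum(s$p_combined < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Write statistics outputs
#'
#' Writes the merged table with per-column one-tailed p-values and the
#' combined statistic appended ("Merged statistics.txt") and a compact
#' per-gene summary ("stats_summary.txt").  Statistics files are derived
#' products and are always rewritten.
#'
#' @param stats A `maex_stats` object.
#' @param root Study-tree root directory.
#' @return Named character vector of the two paths, invisibly.
#' @export
persist_stats <- function(stats, root) {
  table <- stats$table
  s <- stats$summary
  wide <- data.frame(Gene = table$genes, stringsAsFactors = FALSE,
                     check.names = FALSE)
  for (j in seq_len(nrow(table$columns))) {
    wide[[sprintf("ratio:%s", table$columns$label[j])]] <- table$ratios[, j]
  }
  for (j in seq_len(nrow(table$columns))) {
    wide[[sprintf("p:%s", table$columns$label[j])]] <- stats$p_matrix[, j]
  }
  wide$statistic <- s$statistic
  wide$p_combined <- s$p_combined
  wide$sign <- ifelse(is.na(s$sign), "",
                      ifelse(s$sign > 0, "+", ifelse(s$sign < 0, "-", "0")))
  stats_path <- file.path(root, "Merged statistics.txt")
  write_table(wide, stats_path, overwrite = "force")
  summary_path <- file.path(root, "stats_summary.txt")
  write_table(s, summary_path, overwrite = "force")
  invisible(c(stats = stats_path, summary = summary_path))
}
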