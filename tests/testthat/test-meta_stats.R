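test_that("one-tailed pooled t behaves at the null, a strong effect, and n=1", {
  tt <- one_tailed_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$p_one, 0.5)
  expect_equal(tt$direction, 0)

  # oracle values frozen from t.test(..., var.equal = TRUE): t = 11.0227,
  # df = 4, two-sided p = 3.8507e-4
  tt <- one_tailed_t(c(10, 11, 12), c(1, 2, 3))
  expect_equal(tt$direction, 1)
  expect_equal(tt$df, 4)
  expect_equal(tt$t_stat, 11.022703842524301, tolerance = 1e-12)
  expect_equal(tt$p_one, 0.0001925338556832706, tolerance = 1e-10)
  expect_lt(tt$p_one, 0.005)

  # mirrored samples flip the direction, not the p-value
  rev_tt <- one_tailed_t(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rev_tt$direction, -1)
  expect_equal(rev_tt$p_one, tt$p_one)

  expect_false(one_tailed_t(5, c(1, 2, 3))$testable)
  expect_false(one_tailed_t(c(1, 2), c(NA, NA, 3))$testable)

  # missing values are dropped sample-wise
  with_na <- one_tailed_t(c(10, 11, 12, NA), c(1, NA, 2, 3))
  expect_equal(with_na$t_stat, tt$t_stat)
})

test_that("welch flag reproduces stats::t.test under unequal variances", {
  set.seed(1)
  x <- rnorm(8, 1, 3); y <- rnorm(12, 0, 0.5)
  ours <- one_tailed_t(x, y, welch = TRUE)
  ref <- t.test(x, y)
  expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_one, ref$p.value / 2, tolerance = 1e-12)
})

test_that("stouffer combination matches its closed-form worked cases", {
  # single p = 0.5 is a null score
  m <- stouffer_combine(0.5, 1)
  expect_equal(m$z_combined, 0)
  expect_equal(m$p_combined, 1)

  # two concordant p = 0.05: Z = 2 qnorm(.95)/sqrt(2), p ~ 0.0200
  m <- stouffer_combine(c(0.05, 0.05), c(1, 1))
  expect_equal(m$z_combined, 2.32617430735335, tolerance = 1e-10)
  expect_equal(m$p_combined, 0.0200092537161181, tolerance = 1e-10)
  expect_equal(m$direction_consensus, 1)
  expect_equal(m$n_scores, 2L)

  # the printed /N variant halves the score
  mn <- stouffer_combine(c(0.05, 0.05), c(1, 1), denominator = "n")
  expect_equal(mn$z_combined, 1.64485362695147, tolerance = 1e-10)
  expect_equal(mn$p_combined, 2 * pnorm(-1.64485362695147), tolerance = 1e-10)

  # exact cancellation of opposing effects
  m <- stouffer_combine(c(0.05, 0.05), c(1, -1))
  expect_equal(m$z_combined, 0)
  expect_equal(m$p_combined, 1)
  expect_equal(m$direction_consensus, 0)

  # p at 0 is clamped, not fatal
  expect_warning(m0 <- stouffer_combine(c(0, 0.05), c(1, 1)), "clamped")
  expect_true(is.finite(m0$z_combined) && m0$p_combined > 0)
})

test_that("fisher combination matches the chi-square closed form", {
  expect_warning(m <- fisher_combine(1), "clamped")
  expect_equal(m$chi2, 0)
  expect_equal(m$p_combined, 1)
  expect_equal(m$dof, 2L)

  m <- fisher_combine(c(0.05, 0.05), c(1, 1))
  expect_equal(m$chi2, 11.983, tolerance = 1e-4)
  expect_equal(m$p_combined, 0.0174786613677700, tolerance = 1e-10)
  expect_equal(m$p_combined, chisq_sf_even_oracle(m$chi2, 2L), tolerance = 1e-12)
  expect_equal(m$direction_consensus, 1)

  # p = 0.5 replicated: chi2 = 1.386 k, never significant for small k
  for (k in 1:4) {
    m <- fisher_combine(rep(0.5, k), rep(1, k))
    expect_equal(m$chi2, 2 * k * log(2), tolerance = 1e-12)
    expect_equal(m$p_combined, chisq_sf_even_oracle(2 * k * log(2), k),
                 tolerance = 1e-12)
    expect_gt(m$p_combined, 0.05)
  }

  # direction ties yield consensus 0
  expect_equal(fisher_combine(c(.2, .2), c(1, -1))$direction_consensus, 0)
})

test_that("combination is sign-coherent and order-invariant", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(2:9, 1)
    p <- runif(k, 1e-4, 0.6)
    d <- sample(c(-1, 1), k, replace = TRUE)
    s <- stouffer_combine(p, d)
    s_neg <- stouffer_combine(p, -d)
    expect_equal(s_neg$z_combined, -s$z_combined)
    expect_equal(s_neg$p_combined, s$p_combined)
    perm <- sample.int(k)
    s_perm <- stouffer_combine(p[perm], d[perm])
    expect_equal(s_perm$z_combined, s$z_combined)
    f <- fisher_combine(p, d)
    f_perm <- fisher_combine(p[perm], d[perm])
    expect_equal(f_perm$chi2, f$chi2)
    expect_equal(f_perm$p_combined, f$p_combined)
  }
})

test_that("study tests and annotation combine only what the table retains", {
  root <- withr_tempdir()
  generate_tree(synth_config(n_studies = 3, n_genes = 6,
                             effect_genes = c(GENE001 = 1.5), seed = 21), root)
  genes <- read_gene_list(file.path(root, "Genes of interest.txt"))
  refined <- suppressMessages(lapply(scan_study_folders(root), function(f) {
    refine_study(extract_study(f, genes))
  }))
  tests <- study_tests(refined)
  expect_equal(nrow(tests), 6L * 3L)
  expect_true(all(tests$testable))
  expect_true(all(tests$p_one > 0 & tests$p_one <= 0.5))

  merged <- merge_studies(refined, genes)
  ann <- suppressMessages(annotate_merged(merged, tests, stat_config("stouffer")))
  expect_identical(ann$summary$gene_id, merged$genes)
  expect_equal(ann$summary$k_used, rep(3L, 6L))
  expect_equal(dim(ann$p_matrix), c(6L, 3L))
  expect_false(anyNA(ann$p_matrix))
  expect_equal(ann$summary$sign[1], 1)

  # a hand-pruned table restricts the combination to what remains
  pruned <- merged
  pruned$columns <- pruned$columns[-1, , drop = FALSE]
  pruned$ratios <- pruned$ratios[, -1, drop = FALSE]
  ann2 <- suppressMessages(annotate_merged(pruned, tests, stat_config("stouffer")))
  expect_equal(ann2$summary$k_used, rep(2L, 6L))
  expect_equal(ann2$summary$n_studies_used, rep(2L, 6L))
  # and the reduced combination is reproducible by hand
  tg <- tests[tests$gene_id == "GENE001" & tests$label %in% pruned$columns$label, ]
  expect_equal(ann2$summary$p_combined[1],
               stouffer_combine(tg$p_one, tg$direction)$p_combined)

  # gene with zero testable columns gets a missing combined p
  none <- merged
  none$genes <- c(none$genes, "GHOST")
  none$ratios <- rbind(none$ratios, NA)
  ann3 <- suppressMessages(annotate_merged(none, tests, stat_config("fisher")))
  expect_true(is.na(ann3$summary$p_combined[ann3$summary$gene_id == "GHOST"]))
  expect_equal(ann3$summary$k_used[ann3$summary$gene_id == "GHOST"], 0L)

  # optional BH column appears only on request and is monotone-consistent
  ann4 <- suppressMessages(annotate_merged(merged, tests,
                                           stat_config("stouffer", bh = TRUE)))
  expect_true("p_bh" %in% names(ann4$summary))
  expect_true(all(ann4$summary$p_bh >= ann4$summary$p_combined))
  expect_false("p_bh" %in% names(ann$summary))
})

test_that("stats files are written with ratio, p and sign columns", {
  root <- withr_tempdir()
  generate_tree(synth_config(n_studies = 2, n_genes = 4, seed = 8), root)
  res <- suppressMessages(run_pipeline(run_config(root)))
  paths <- c(file.path(root, "Merged statistics.txt"),
             file.path(root, "stats_summary.txt"))
  expect_true(all(file.exists(paths)))
  wide <- utils::read.delim(paths[1], check.names = FALSE)
  expect_true(all(c("Gene", "statistic", "p_combined", "sign") %in% names(wide)))
  expect_equal(sum(startsWith(names(wide), "p:")), 2L)
  summ <- utils::read.delim(paths[2])
  expect_identical(summ$gene_id, res$stats$summary$gene_id)
  expect_equal(summ$p_combined, res$stats$summary$p_combined, tolerance = 1e-12)
})
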