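test_that("log2 detection uses the max-value rule with <= boundary", {
  m <- expression_from_matrix(matrix(c(3.2, 14.2, NA), 1))
  expect_true(detect_log2(m, 50))
  expect_false(detect_log2(expression_from_matrix(matrix(c(12, 20000), 1)), 50))
  # boundary: max exactly at the threshold counts as log2
  expect_true(detect_log2(expression_from_matrix(matrix(c(1, 50), 1)), 50))
  expect_false(detect_log2(expression_from_matrix(matrix(c(1, 50 + 1e-9), 1)), 50))
  expect_error(detect_log2(expression_from_matrix(matrix(NA_real_, 2, 2))),
               class = "maex_validation_error")
})

test_that("log2 transform is exact, identity-safe and rejects nonpositives", {
  m <- expression_from_matrix(matrix(c(8, 1, 0.5, NA), 2,
                                     dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  out <- to_log2(m, FALSE)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(out$values[1, 2], -1)
  expect_true(is.na(out$values[2, 2]))
  expect_identical(out$scale, "LOG2")

  expect_identical(to_log2(m, TRUE)$values, m$values)

  m$values[2, 1] <- 0
  err <- expect_error(to_log2(m, FALSE), class = "maex_validation_error")
  expect_match(conditionMessage(err), "probe p2, sample s1")
})

test_that("suffix priority ranks match a brute-force matcher", {
  suffixes <- c("_at", "_s_at")
  expect_identical(probe_priority("1001_at", suffixes), 0L)
  # "_s_at" also ends with "_at": longest suffix must win
  expect_identical(probe_priority("1001_s_at", suffixes), 1L)
  expect_identical(probe_priority("AFFX-ctrl", c("_at")), NA_integer_)
  expect_identical(probe_priority(c("a", "b"), character(0)), c(0L, 0L))

  # exhaustive cross-check over a fixture of IDs x suffix lists
  ids <- c("1001_at", "1001_s_at", "1001_x_at", "AFFX-ctrl", "g_at_s_at", "_at")
  lists <- list(c("_at", "_s_at"), c("_s_at", "_at"),
                c("_x_at", "_s_at", "_at"), c("_st"))
  for (sfx in lists) {
    got <- probe_priority(ids, sfx)
    want <- vapply(ids, probe_priority_brute, integer(1), suffixes = sfx)
    expect_identical(got, unname(want))
  }
})

test_that("probe selection obeys priority, control brightness and ties", {
  cv <- rbind(c(5.1, 5.2, 5.0), c(7.3, 7.2, 7.4))
  # equal rank: higher control mean wins
  expect_identical(select_probe(c("p1_at", "p2_at"), cv, c("_at")), 2L)
  # priority dominates control brightness
  cv2 <- rbind(c(5, 5, 5), c(9, 9, 9))
  expect_identical(select_probe(c("p1_at", "p2_s_at"), cv2, c("_at", "_s_at")), 1L)
  # single candidate returns itself
  expect_identical(select_probe("p1_at", cv[1, , drop = FALSE], c("_at")), 1L)
  # exact tie: first in annotation order, logged
  cv3 <- rbind(c(6, 6), c(6, 6))
  expect_message(sel <- select_probe(c("pA_at", "pB_at"), cv3, c("_at")), "tie")
  expect_identical(sel, 1L)
  # all excluded
  expect_identical(select_probe(c("pA_st"), cv[1, , drop = FALSE], c("_at")),
                   NA_integer_)
  # median centering can change the winner
  cvm <- rbind(c(10, 3, 3), c(4, 4, 4))
  expect_identical(select_probe(c("a_at", "b_at"), cvm, c("_at"), "mean"), 1L)
  expect_identical(select_probe(c("a_at", "b_at"), cvm, c("_at"), "median"), 2L)
})

test_that("selection is invariant to candidate order and rank-minimal", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    ids <- sprintf("g_p%d%s", seq_len(n),
                   sample(c("_at", "_s_at", "_x_at"), n, replace = TRUE))
    cv <- matrix(rnorm(n * 4, 8), n)
    sfx <- c("_at", "_s_at", "_x_at")
    sel <- select_probe(ids, cv, sfx)
    ranks <- probe_priority(ids, sfx)
    expect_true(ranks[sel] <= min(ranks, na.rm = TRUE))
    perm <- sample.int(n)
    sel_p <- select_probe(ids[perm], cv[perm, , drop = FALSE], sfx)
    expect_identical(ids[perm][sel_p], ids[sel])
  }
})

test_that("ratios are log2 center differences, clustered by design", {
  root <- make_basic_tree(withr_tempdir())
  folder <- scan_study_folders(root)[[1]]
  ex <- extract_study(folder, c("GA", "GB"))
  ref <- refine_study(ex, refine_config())
  # GA selects the brighter-control _s_at probe (no priorities defined)
  expect_identical(ref$genes$probe_id[ref$genes$gene_id == "GA"], "pA2_s_at")
  expect_equal(unname(ref$ratios["GA", "disease"]), 7 - 9)
  expect_equal(unname(ref$ratios["GB", "disease"]), 7 - 5)
  expect_equal(unname(ref$n["GA", ]), c(control = 3L, disease = 3L),
               ignore_attr = TRUE)

  # disease identical to control -> ratio 0
  root2 <- withr_tempdir()
  write_study_folder(root2, 1L, "S",
                     matrix_lines = c("ID\tc1\tc2\td1\td2",
                                      "p1\t4\t6\t4\t6"),
                     annotation_lines = "GA\tp1",
                     design_lines = c("CONTROL:ctrl\tc1\tc2", "dis\td1\td2"))
  ref2 <- refine_study(extract_study(scan_study_folders(root2)[[1]], "GA"))
  expect_equal(unname(ref2$ratios["GA", "dis"]), 0)
})

test_that("scrambled sample columns give identical ratios", {
  base <- withr_tempdir(); scram <- withr_tempdir()
  generate_tree(synth_config(n_studies = 2, n_genes = 8, seed = 11,
                             scramble_columns = FALSE), base)
  generate_tree(synth_config(n_studies = 2, n_genes = 8, seed = 11,
                             scramble_columns = TRUE), scram)
  ref <- function(root) {
    genes <- read_gene_list(file.path(root, "Genes of interest.txt"))
    lapply(scan_study_folders(root),
           function(f) refine_study(extract_study(f, genes)))
  }
  suppressMessages({
    a <- merge_studies(ref(base))
    b <- merge_studies(ref(scram))
  })
  expect_equal(a$ratios, b$ratios)
})

test_that("linear input refines identically to its pre-logged counterpart", {
  lin <- withr_tempdir(); logd <- withr_tempdir()
  generate_tree(synth_config(n_studies = 3, n_genes = 10, seed = 5,
                             linear_scale_studies = c(1L, 3L)), lin)
  generate_tree(synth_config(n_studies = 3, n_genes = 10, seed = 5), logd)
  run <- function(root, log_mode) {
    genes <- read_gene_list(file.path(root, "Genes of interest.txt"))
    refined <- lapply(scan_study_folders(root), function(f) {
      refine_study(extract_study(f, genes),
                   refine_config(log_mode = log_mode))
    })
    merge_studies(refined, genes)$ratios
  }
  suppressMessages({
    r_auto <- run(lin, "auto")
    r_manual <- run(lin, "manual")
    r_log <- run(logd, "auto")
  })
  expect_equal(r_auto, r_log, tolerance = 1e-9)
  expect_equal(r_manual, r_log, tolerance = 1e-9)
})

test_that("ratios are antisymmetric under swapping group and control", {
  root <- withr_tempdir()
  lines <- c("ID\ta1\ta2\ta3\tb1\tb2\tb3",
             "p1\t8\t8.5\t7.5\t6\t6.5\t5.5")
  write_study_folder(root, 1L, "S", matrix_lines = lines,
                     annotation_lines = "GA\tp1",
                     design_lines = c("CONTROL:A\ta1\ta2\ta3", "B\tb1\tb2\tb3"))
  write_study_folder(root, 2L, "S2", matrix_lines = lines,
                     annotation_lines = "GA\tp1",
                     design_lines = c("A\ta1\ta2\ta3", "CONTROL:B\tb1\tb2\tb3"))
  folders <- scan_study_folders(root)
  r1 <- refine_study(extract_study(folders[[1]], "GA"))
  r2 <- refine_study(extract_study(folders[[2]], "GA"))
  expect_equal(unname(r1$ratios["GA", "B"]), -unname(r2$ratios["GA", "A"]))
})

test_that("a fully excluded gene is dropped with a warning", {
  root <- withr_tempdir()
  write_study_folder(root, 1L, "S",
                     matrix_lines = c("ID\tc1\tc2\td1\td2", "pX_st\t1\t2\t3\t4",
                                      "pY_at\t1\t2\t3\t4"),
                     annotation_lines = c("GA\tpX_st\t\t_at", "GB\tpY_at"),
                     design_lines = c("CONTROL:c\tc1\tc2", "d\td1\td2"))
  ex <- extract_study(scan_study_folders(root)[[1]], c("GA", "GB"))
  expect_warning(ref <- refine_study(ex), "GA")
  expect_identical(ref$genes$gene_id, "GB")
})

test_that("refined outputs respect the preserve policy", {
  root <- make_basic_tree(withr_tempdir())
  folder <- scan_study_folders(root)[[1]]
  ref <- refine_study(extract_study(folder, c("GA", "GB")))
  path <- persist_refined(ref, root)
  content <- readLines(path)
  expect_message(persist_refined(ref, root), "preserved")
  expect_identical(readLines(path), content)
})
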