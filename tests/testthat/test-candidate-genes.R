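test_that("fold changes follow the closed-form ddCt arithmetic", {
  ct <- tibble::tibble(sample = c("tumor", "ctrl"),
                       ct_target = c(20, 22), ct_reference = c(15, 15))
  res <- ddct_fold_change(ct, calibrator = "ctrl")
  expect_equal(res$delta_delta_ct[res$sample == "tumor"], -2)
  expect_equal(res$fold_change[res$sample == "tumor"], 4)
  expect_equal(res$fold_change[res$sample == "ctrl"], 1)
})

test_that("replicate Ct rows are averaged before the delta step", {
  ct <- tibble::tibble(sample = c("a", "a", "a", "cal"),
                       ct_target = c(20.0, 20.2, 19.8, 21),
                       ct_reference = c(15, 15, 15, 15))
  res <- ddct_fold_change(ct, "cal")
  expect_equal(res$delta_ct[res$sample == "a"], 5)
  expect_equal(res$fold_change[res$sample == "a"], 2)
})

test_that("ddCt is invariant to a shared Ct offset and bounds its inputs", {
  ct <- tibble::tibble(sample = c("a", "cal"),
                       ct_target = c(18, 20), ct_reference = c(14, 15))
  shifted <- dplyr::mutate(ct, ct_target = ct_target + 3,
                           ct_reference = ct_reference + 3)
  expect_equal(ddct_fold_change(ct, "cal")$fold_change,
               ddct_fold_change(shifted, "cal")$fold_change)
  expect_error(ddct_fold_change(
    dplyr::mutate(ct, ct_target = c(50, 20)), "cal"), "Ct")
  expect_error(ddct_fold_change(ct, "nope"), "calibrator")
})

test_that("a survival-linked gene is recovered by the Cox table", {
  set.seed(81)
  n <- 400
  lp <- rnorm(n)
  cl <- simulate_survival(stats::setNames(lp, sprintf("S%03d", 1:n)),
                          baseline_hazard = 6e-4, censor_rate = 4e-4)
  expr <- rbind(linked = lp, noise = rnorm(n))
  colnames(expr) <- cl$sample
  res <- gene_cox_table(expr, cl, c("linked", "noise", "absent"))
  expect_equal(attr(res, "absent"), "absent")
  linked <- res[res$gene == "linked", ]
  expect_gt(linked$hr, 1)
  expect_lt(linked$p_univariate, 0.001)
  expect_lt(linked$km_logrank_p, 0.01)
})

test_that("halving the expression scale doubles the log hazard ratio", {
  set.seed(82)
  n <- 300
  g <- rnorm(n)
  cl <- simulate_survival(stats::setNames(0.7 * g, sprintf("S%03d", 1:n)),
                          baseline_hazard = 6e-4, censor_rate = 4e-4)
  expr <- rbind(unit = g, doubled = 2 * g)
  colnames(expr) <- cl$sample
  res <- suppressWarnings(gene_cox_table(expr, cl, c("unit", "doubled")))
  expect_equal(log(res$hr[res$gene == "unit"]),
               2 * log(res$hr[res$gene == "doubled"]), tolerance = 1e-6)
})

test_that("lasso prioritization ranks the true effect first, deterministically", {
  set.seed(83)
  n <- 400
  g_true <- rnorm(n)
  cl <- simulate_survival(stats::setNames(1.0 * g_true, sprintf("S%03d", 1:n)),
                          baseline_hazard = 6e-4, censor_rate = 4e-4)
  expr <- rbind(true = g_true, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                n4 = rnorm(n))
  colnames(expr) <- cl$sample
  r1 <- prioritize_genes(expr, cl, rownames(expr), seed = 4)
  expect_equal(r1$gene[1], "true")
  r2 <- prioritize_genes(expr, cl, rownames(expr), seed = 4)
  expect_identical(r1, r2)

  dup <- rbind(expr, true_copy = g_true)
  r3 <- suppressMessages(prioritize_genes(dup, cl, rownames(dup), seed = 4))
  expect_false("true_copy" %in% r3$gene)
})

test_that("gene correlations honour rank reversal and independence", {
  set.seed(84)
  n <- 500
  g <- rnorm(n)
  expr <- rbind(a = g, b = -g^3, c = rnorm(n))
  colnames(expr) <- sprintf("S%03d", 1:n)
  gc <- gene_correlations(expr, c("a", "b", "c"), method = "spearman")
  expect_equal(diag(gc$matrix), rep(1, 3), ignore_attr = TRUE)
  expect_equal(gc$matrix["a", "b"], -1)
  expect_lt(abs(gc$matrix["a", "c"]), 0.12)
  expect_equal(gc$matrix, t(gc$matrix))

  const <- rbind(a = g, flat = rep(1, n))
  colnames(const) <- colnames(expr)
  expect_warning(gc2 <- gene_correlations(const, c("a", "flat")),
                 "constant")
  expect_true(is.na(gc2$matrix["a", "flat"]))
})
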