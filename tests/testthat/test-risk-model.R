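make_model <- function(pairs, coefs) {
  ids <- vapply(pairs, function(p) paste(p, collapse = "|"), "")
  structure(list(
    pairs = tibble::tibble(
      pair_id = ids,
      gene_a = vapply(pairs, `[`, "", 1),
      gene_b = vapply(pairs, `[`, "", 2),
      coefficient = coefs),
    method = "lasso", lambda = 0.01, nfolds = 10, seed = 1L,
    cutoff = NA_real_, training_auc = NA_real_), class = "irgp_model")
}

test_that("risk scores are coefficient-weighted indicator sums", {
  model <- make_model(list(c("A", "B"), c("C", "D")), c(0.8, -0.5))
  expr <- matrix(c(5, 1,   # A > B and C > D in S1; neither in S2
                   1, 5,
                   4, 1,
                   1, 4), nrow = 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  sc <- score_samples(model, expr)
  expect_equal(sc$risk_score, c(0.3, 0))
})

test_that("scoring is additive over sample-set concatenation", {
  model <- make_model(list(c("G01", "G02"), c("G03", "G04")), c(1.2, -0.4))
  expr <- tiny_expr(4, 10, seed = 6)
  both <- score_samples(model, expr)
  left <- score_samples(model, expr[, 1:4])
  right <- score_samples(model, expr[, 5:10])
  expect_equal(both$risk_score, c(left$risk_score, right$risk_score))
})

test_that("scoring fails below 90% pair coverage and logs missing pairs", {
  model <- make_model(list(c("A", "B"), c("C", "D")), c(1, 1))
  expr <- matrix(c(1, 2), 1, 2, dimnames = list("A", c("S1", "S2")))
  expect_error(score_samples(model, expr), "90% coverage")
})

test_that("univariate screening recovers a planted effect and skips constants", {
  set.seed(61)
  n <- 400
  s <- rbinom(n, 1, 0.5)
  cl <- simulate_survival(stats::setNames(1.0 * s, sprintf("S%03d", 1:n)),
                          baseline_hazard = 6e-4, censor_rate = 4e-4)
  x <- rbind(planted = s, const = rep(1, n),
             noise = rbinom(n, 1, 0.5))
  colnames(x) <- cl$sample
  expect_warning(res <- univariate_screen(x, cl, p_threshold = 0.01),
                 "constant")
  expect_false("const" %in% res$feature)
  planted <- res[res$feature == "planted", ]
  expect_true(planted$keep)
  expect_gt(planted$hr, 1)
})

test_that("null features are retained at about the nominal rate", {
  set.seed(62)
  n <- 150
  cl <- simulate_survival(rep(0, n), baseline_hazard = 6e-4,
                          censor_rate = 4e-4)
  x <- matrix(rbinom(200 * n, 1, 0.5), 200, n,
              dimnames = list(sprintf("F%03d", 1:200), cl$sample))
  res <- univariate_screen(x, cl, p_threshold = 0.05)
  expect_lt(mean(res$keep), 0.12)  # ~5% expected
})

test_that("the lasso fit is deterministic and collapses duplicates", {
  set.seed(63)
  n <- 200
  s1 <- rbinom(n, 1, 0.5); s2 <- rbinom(n, 1, 0.5)
  cl <- simulate_survival(stats::setNames(s1 - 0.8 * s2, sprintf("S%03d", 1:n)),
                          baseline_hazard = 8e-4, censor_rate = 2e-4)
  x <- rbind(`A|B` = s1, `C|D` = s2, `E|F` = s1, `G|H` = rbinom(n, 1, 0.5))
  colnames(x) <- cl$sample
  expect_message(m1 <- fit_model(x, cl, seed = 5), "duplicated")
  m2 <- suppressMessages(fit_model(x, cl, seed = 5))
  expect_identical(m1$pairs, m2$pairs)
  # the duplicate of A|B (E|F) was dropped before the fit
  expect_false("E|F" %in% m1$pairs$pair_id)
  expect_true("A|B" %in% m1$pairs$pair_id)
})

test_that("perfectly separating scores give AUC 1 and a separating cutoff", {
  sc <- tibble::tibble(sample = sprintf("S%d", 1:8),
                       risk_score = c(1, 2, 3, 4, 10, 11, 12, 13))
  cl <- clinical_from_labels(sc$sample, c(0, 0, 0, 0, 1, 1, 1, 1))
  cut <- optimal_cutoff(sc, cl)
  expect_equal(cut$auc, 1)
  expect_gt(cut$cutoff, 4)
  expect_lt(cut$cutoff, 10)
})

test_that("uninformative scores give a null AUC", {
  set.seed(64)
  n <- 2000
  sc <- tibble::tibble(sample = sprintf("S%04d", 1:n), risk_score = rnorm(n))
  cl <- clinical_from_labels(sc$sample, rbinom(n, 1, 0.4))
  expect_equal(optimal_cutoff(sc, cl)$auc, 0.5, tolerance = 0.03 / 0.5)
})

test_that("censoring before the horizon excludes a sample from labelling", {
  sc <- tibble::tibble(sample = sprintf("S%d", 1:5),
                       risk_score = c(1, 2, 3, 4, 5))
  cl <- tibble::tibble(sample = sc$sample,
                       os_time = c(100, 2000, 100, 2000, 90),
                       os_event = c(1, 0, 1, 0, 0))  # S5 censored early
  cut <- optimal_cutoff(sc, cl)
  expect_equal(cut$n_used, 4)
  expect_equal(cut$n_excluded, 1)
  expect_error(optimal_cutoff(sc[1, ], cl[1, ]), "one outcome class")
})

test_that("log-rank results match survdiff conventions on simple cases", {
  # identical event patterns in both groups carry no signal
  cl <- tibble::tibble(sample = sprintf("S%d", 1:6),
                       os_time = rep(c(100, 200, 300), 2),
                       os_event = rep(1, 6))
  grp <- tibble::tibble(sample = cl$sample, group = rep(c("a", "b"), 3))
  res <- compare_groups(grp, cl)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  # all deaths in group A precede group B: statistic equals the hand oracle
  cl2 <- tibble::tibble(sample = sprintf("S%d", 1:6),
                        os_time = c(1, 2, 3, 4, 5, 6), os_event = rep(1, 6))
  grp2 <- tibble::tibble(sample = cl2$sample,
                         group = rep(c("A", "B"), each = 3))
  res2 <- compare_groups(grp2, cl2)
  expect_equal(res2$chisq,
               logrank_chisq_oracle(cl2$os_time, cl2$os_event, grp2$group),
               tolerance = 1e-9)
  # invariant to swapping the group labels
  grp2_swapped <- dplyr::mutate(grp2, group = ifelse(group == "A", "B", "A"))
  expect_equal(compare_groups(grp2_swapped, cl2)$chisq, res2$chisq)
})

test_that("KM curves start at one and never increase", {
  set.seed(65)
  cl <- simulate_survival(rep(0, 80), 6e-4, 4e-4)
  grp <- tibble::tibble(sample = cl$sample, group = rep(c("x", "y"), 40))
  km <- compare_groups(grp, cl)$km
  for (g in c("x", "y")) {
    s <- km$surv[km$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("a noiseless risk score is an independent prognostic factor", {
  set.seed(66)
  n <- 400
  lp <- rnorm(n)
  cl <- simulate_survival(stats::setNames(lp, sprintf("S%03d", 1:n)),
                          baseline_hazard = 6e-4, censor_rate = 4e-4)
  cl$age <- round(rnorm(n, 65, 8))
  cl$stage <- sample(c("I", "II", "III"), n, replace = TRUE)
  sc <- tibble::tibble(sample = cl$sample, risk_score = lp)
  res <- independence_analysis(sc, cl)
  multi <- res$multivariate[res$multivariate$term == "risk_score", ]
  expect_gt(multi$hr, 1)
  expect_lt(multi$p, 0.05)

  cl$age2 <- cl$age  # exact copy triggers the collinearity guard
  expect_error(independence_analysis(sc, cl, c("age", "age2")), "collinear")
})
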