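small_spec <- function(seed = 7, ...) {
  cohort_spec(n_samples = 60, n_genes = 30, n_immune_genes = 8,
              n_driver_pairs = 2, n_probes = 5, n_normal = 5,
              mut_mean = 40, seed = seed, ...)
}

test_that("identical seeds reproduce the cohort exactly", {
  c1 <- generate_cohort(small_spec(seed = 7))
  c2 <- generate_cohort(small_spec(seed = 7))
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$maf, c2$maf)
  expect_identical(c1$methylation$beta, c2$methylation$beta)
  c3 <- generate_cohort(small_spec(seed = 8))
  expect_false(identical(c1$expression, c3$expression))
})

test_that("cohorts round-trip through the file readers", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_identical(read_expression(file.path(dir, "expression.tsv")),
                   co$expression)
  expect_identical(read_clinical(file.path(dir, "clinical.tsv"))$os_time,
                   co$clinical$os_time)
  maf <- read_maf(file.path(dir, "mutations.maf"))
  expect_equal(nrow(maf), nrow(co$maf))
  expect_equal(read_gene_list(file.path(dir, "immune_genes.txt")),
               co$immune_genes)
})

test_that("driver pairs naming absent genes are rejected", {
  expect_error(
    cohort_spec(n_genes = 10, n_immune_genes = 4,
                driver_pairs = tibble::tibble(gene_a = "G0001",
                                              gene_b = "NOPE", beta = 1)),
    "NOPE")
})

test_that("exponential survival has the closed-form median", {
  set.seed(11)
  lambda <- 1e-3
  cl <- simulate_survival(rep(0, 10000), baseline_hazard = lambda,
                          censor_rate = 0)
  expect_equal(sum(cl$os_event), 10000)  # no censoring in the limit
  expect_equal(median(cl$os_time), log(2) / lambda, tolerance = 0.05)
})

test_that("a standard PH fit recovers the simulated hazard ratio", {
  set.seed(12)
  lp <- rep(c(0, 1), 5000)
  cl <- simulate_survival(lp, baseline_hazard = 5e-4, censor_rate = 2e-4)
  fit <- survival::coxph(survival::Surv(cl$os_time, cl$os_event) ~ lp)
  expect_equal(unname(exp(coef(fit))), exp(1), tolerance = 0.05)
})

test_that("survival simulation validates its rates", {
  expect_error(simulate_survival(c(0, 1), baseline_hazard = 0,
                                 censor_rate = 1e-4), "positive")
  expect_error(simulate_survival(c(0, NA), 1e-3, 1e-4), "finite")
})

test_that("a planted pair effect raises the event rate in its stratum", {
  spec <- cohort_spec(
    n_samples = 2000, n_genes = 20, n_immune_genes = 4, n_probes = 4,
    n_normal = 4, mut_mean = 40, tmb_beta = 0,
    driver_pairs = tibble::tibble(gene_a = "G0001", gene_b = "G0002",
                                  beta = 1),
    deg_shifts = tibble::tibble(gene = character(), group = character(),
                                shift = numeric()),
    censor_rate = 0, seed = 21)
  co <- generate_cohort(spec)
  s <- as.numeric(co$expression["G0001", ] > co$expression["G0002", ])
  horizon <- 1000
  dead <- co$clinical$os_event == 1 & co$clinical$os_time <= horizon
  expect_gt(mean(dead[s == 1]), mean(dead[s == 0]))
})

test_that("null cohorts show no spurious survival signal", {
  set.seed(31)
  n_sig <- 0
  for (r in 1:100) {
    cl <- simulate_survival(rep(0, 60), baseline_hazard = 6e-4,
                            censor_rate = 4e-4)
    grp <- tibble::tibble(sample = cl$sample,
                          group = sample(rep(c("a", "b"), 30)))
    if (compare_groups(grp, cl)$p < 0.05) n_sig <- n_sig + 1
  }
  # a calibrated 5% test stays under 10/100 with probability > 0.99
  expect_lte(n_sig, 10)
})

test_that("mutation simulation honours the class distribution and seed", {
  maf <- simulate_maf(c("S1", "S2"), mut_mean = 50,
                      class_probs = c(Missense_Mutation = 1), seed = 3)
  expect_true(all(maf$variant_classification == "Missense_Mutation"))
  expect_true(all(maf$variant_type == "SNP"))
  expect_identical(simulate_maf(c("S1", "S2"), mut_mean = 50, seed = 5),
                   simulate_maf(c("S1", "S2"), mut_mean = 50, seed = 5))
})

test_that("simulated methylation respects the unit interval and null links", {
  expr <- tiny_expr(4, 300, seed = 9)
  links <- tibble::tibble(probe = "cg1", gene = "G01", rho = 0)
  sim <- simulate_methylation(links, expr, n_probes = 6, n_normal = 10,
                              seed = 13)
  expect_true(all(sim$meth$beta >= 0 & sim$meth$beta <= 1))
  r <- cor(sim$meth$beta["cg1", colnames(expr)], expr["G01", ])
  expect_lt(abs(r), 0.12)
  expect_error(simulate_methylation(
    tibble::tibble(probe = "cg1", gene = "G01", rho = 1.4), expr), "rho")
})
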