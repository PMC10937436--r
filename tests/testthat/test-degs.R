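test_that("rank-sum p-values match the reference implementation", {
  set.seed(71)
  for (r in 1:30) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    if (r %% 3 == 0) {  # inject ties
      x <- round(x); y <- round(y)
    }
    mat <- matrix(c(x, y), nrow = 1)
    got <- irgprog:::rank_sum_p(mat, seq_len(n1), n1 + seq_len(n2))
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(unname(got), ref, tolerance = 1e-12)
  }
})

test_that("genes identical across groups are never DEGs", {
  expr <- rbind(flat = rep(5, 12), varying = c(rnorm(6, 0), rnorm(6, 3)))
  colnames(expr) <- sprintf("S%02d", 1:12)
  grp <- tibble::tibble(sample = colnames(expr),
                        group = rep(c("high", "low"), each = 6))
  res <- differential_expression(expr, grp)
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_false(res$deg[res$gene == "flat"])
})

test_that("swapping group labels flips signs but not p-values", {
  set.seed(72)
  expr <- matrix(rnorm(50 * 20), 50, 20,
                 dimnames = list(sprintf("G%02d", 1:50),
                                 sprintf("S%02d", 1:20)))
  grp <- tibble::tibble(sample = colnames(expr),
                        group = factor(rep(c("a", "b"), each = 10),
                                       c("a", "b")))
  grp_sw <- dplyr::mutate(grp, group = factor(
    ifelse(group == "a", "b", "a"), c("a", "b")))
  r1 <- differential_expression(expr, grp)
  r2 <- differential_expression(expr, grp_sw)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$log_fc, -r2$log_fc)
  expect_true(all(r1$direction != r2$direction | r1$log_fc == 0))
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(73)
  expr <- matrix(rnorm(100 * 12), 100, 12,
                 dimnames = list(sprintf("G%03d", 1:100),
                                 sprintf("S%02d", 1:12)))
  grp <- setNames(rep(c("a", "b"), each = 6), colnames(expr))
  res <- differential_expression(expr, grp)
  expect_equal(order(res$p), order(res$fdr, res$p))
  expect_true(all(res$fdr >= res$p))
})

test_that("a planted shift is detected at cohort scale", {
  set.seed(74)
  expr <- matrix(rnorm(200 * 200), 200, 200,
                 dimnames = list(sprintf("G%03d", 1:200),
                                 sprintf("S%03d", 1:200)))
  grp <- setNames(rep(c("high", "low"), each = 100), colnames(expr))
  expr["G001", grp == "high"] <- expr["G001", grp == "high"] + 1.5
  res <- differential_expression(expr, grp)
  expect_true(res$deg[res$gene == "G001"])
  expect_equal(res$direction[res$gene == "G001"], "up")
})

test_that("DEG set intersection reports common genes and region counts", {
  res <- intersect_deg_sets(list(one = c("A", "B", "C"),
                                 two = c("B", "C", "D")))
  expect_equal(res$common, c("B", "C"))
  counts <- setNames(res$region_counts$n, res$region_counts$pattern)
  expect_equal(counts[["one"]], 1L)
  expect_equal(counts[["one&two"]], 2L)
  expect_equal(counts[["two"]], 1L)

  expect_equal(intersect_deg_sets(list(a = c("X"), b = c("Y")))$common,
               character())
  expect_equal(intersect_deg_sets(list(a = c("X", "Y"), b = c("X", "Y")))$common,
               c("X", "Y"))
  expect_warning(intersect_deg_sets(list(a = character(), b = "X")), "empty")
})

test_that("immune DEG selection intersects with the gene list", {
  deg <- tibble::tibble(gene = c("A", "B", "C"), log_fc = 1, p = 0.01,
                        fdr = 0.01, direction = "up",
                        deg = c(TRUE, TRUE, FALSE))
  expect_equal(select_immune_degs(deg, c("B", "C", "D")), "B")
  expect_equal(select_immune_degs(deg, character()), character())
  expect_setequal(select_immune_degs(deg, c("A", "B", "C")), c("A", "B"))
})
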