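test_that("substitution classes collapse purine references to the pyrimidine strand", {
  maf <- tiny_maf(sample = c("S1", "S1", "S2", "S2"),
                  gene = c("A", "B", "C", "D"),
                  classification = c("Missense_Mutation", "Missense_Mutation",
                                     "Missense_Mutation", "Frame_Shift_Del"),
                  type = c("SNP", "SNP", "SNP", "DEL"),
                  ref = c("C", "C", "G", "A"),
                  alt = c("T", "T", "A", "-"))
  vs <- summarize_variants(maf)
  expect_equal(vs$by_snv_class$n[vs$by_snv_class$snv_class == "C>T"], 3L)
  expect_equal(vs$by_type$n[vs$by_type$variant_type == "SNP"], 3L)
  expect_equal(vs$by_type$n[vs$by_type$variant_type == "DEL"], 1L)
})

test_that("classification counts conserve the record total", {
  maf <- tiny_maf("S1", "A", "In_Frame_Ins", "INS", "-", "G")
  vs <- summarize_variants(maf)
  expect_equal(vs$by_classification$n, 1L)
  expect_equal(vs$by_classification$variant_classification, "In_Frame_Ins")

  maf2 <- random_maf(60, seed = 4)
  vs2 <- summarize_variants(maf2)
  expect_equal(sum(vs2$by_classification$n), nrow(maf2))
  expect_equal(sum(vs2$per_sample$n), nrow(maf2))
})

test_that("top genes count distinct mutated samples with alphabetical ties", {
  maf <- tiny_maf(sample = c("S1", "S1", "S2", "S1"),
                  gene = c("ZZZ", "ZZZ", "AAA", "AAA"),
                  classification = rep("Missense_Mutation", 4))
  tg <- summarize_variants(maf)$top_genes
  # ZZZ is mutated twice in S1 but counts one distinct sample
  expect_equal(tg$gene, c("AAA", "ZZZ"))
  expect_equal(tg$n_mutated_samples, c(2L, 1L))

  maf_tie <- tiny_maf(sample = c("S1", "S2"), gene = c("BBB", "AAA"),
                      classification = rep("Missense_Mutation", 2))
  expect_equal(summarize_variants(maf_tie)$top_genes$gene, c("AAA", "BBB"))
})

test_that("TMB is the nonsynonymous count over the exome size", {
  maf <- tiny_maf(sample = rep("S1", 24),
                  gene = sprintf("G%d", 1:24),
                  classification = c(rep("Missense_Mutation", 19),
                                     rep("Silent", 5)))
  expect_equal(compute_tmb(maf, exome_mb = 38)$tmb, 0.5)
  expect_equal(compute_tmb(maf, exome_mb = 38, nonsyn_only = FALSE)$tmb,
               24 / 38)
  expect_warning(
    tmb <- compute_tmb(maf, samples = c("S1", "S2")), "S2")
  expect_equal(tmb$tmb[tmb$sample == "S2"], 0)
})

test_that("TMB equals a brute-force filter-and-count oracle", {
  for (r in 1:20) {
    maf <- random_maf(n_records = 40, n_samples = 6, seed = 100 + r)
    got <- compute_tmb(maf, exome_mb = 38)
    for (i in seq_len(nrow(got))) {
      rows <- maf[maf$sample == got$sample[i], ]
      expected <- sum(rows$variant_classification %in%
                        nonsynonymous_classes()) / 38
      expect_identical(got$tmb[i], expected)
    }
  }
})

test_that("median split sends ties to the low group", {
  t1 <- tibble::tibble(sample = paste0("S", 1:4), tmb = c(1, 2, 3, 4))
  g1 <- split_by_median(t1)
  expect_equal(g1$group, c("low", "low", "high", "high"))

  t2 <- tibble::tibble(sample = paste0("S", 1:4), tmb = c(1, 2, 2, 3))
  g2 <- split_by_median(t2)
  expect_equal(g2$group[g2$tmb == 2], c("low", "low"))
  expect_equal(sum(g2$group == "high"), 1)

  t3 <- tibble::tibble(sample = paste0("S", 1:3), tmb = c(5, 5, 5))
  expect_error(split_by_median(t3), "degenerate")
})

test_that("disjoint mutation patterns are called mutually exclusive", {
  # two genes mutated in disjoint halves of a 10-sample cohort
  maf <- tiny_maf(sample = paste0("S", 1:10),
                  gene = rep(c("A", "B"), each = 5),
                  classification = rep("Missense_Mutation", 10))
  res <- mutation_interactions(maf, top_n = 2)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$label, "mutually_exclusive")

  # identical mutation vectors co-occur with infinite odds ratio
  maf2 <- tiny_maf(sample = rep(paste0("S", 1:8), 2),
                   gene = rep(c("A", "B"), each = 8),
                   classification = rep("Missense_Mutation", 16))
  maf2 <- dplyr::bind_rows(maf2, tiny_maf("S9", "C", "Missense_Mutation"))
  res2 <- mutation_interactions(maf2, top_n = 3)
  ab <- res2[res2$gene_a == "A" & res2$gene_b == "B", ]
  expect_equal(ab$odds_ratio, Inf)
  expect_equal(ab$label, "co-occurrence")
})

test_that("interaction p-values are symmetric under sample relabelling", {
  maf <- random_maf(n_records = 50, n_samples = 8, seed = 77)
  res <- mutation_interactions(maf, top_n = 4)
  relabel <- setNames(sprintf("T%d", 8:1), sprintf("S%d", 1:8))
  maf2 <- dplyr::mutate(maf, sample = unname(relabel[sample]))
  res2 <- mutation_interactions(maf2, top_n = 4)
  expect_equal(res$p, res2$p)
  expect_equal(res$odds_ratio, res2$odds_ratio)
})
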