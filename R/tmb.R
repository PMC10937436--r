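#' Nonsynonymous variant classes counted in TMB
#'
#' The nine protein-altering classes counted by default when computing tumor
#' mutational burden. Silent and flank/UTR classes are excluded, following
#' the convention that TMB counts nonsynonymous events.
#'
#' @return Character vector of variant classifications.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
    "In_Frame_Ins", "Translation_Start_Site")
}

snv_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# map a substitution to its pyrimidine-strand equivalent (G>A -> C>T etc.)
complement_substitution <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(comp[substr(x, 1, 1)], ">", comp[substr(x, 3, 3)])
}

collapse_substitution <- function(ref, alt) {
  valid <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  out <- rep(NA_character_, length(ref))
  sub <- paste0(ref, ">", alt)
  purine <- ref %in% c("A", "G")
  out[valid & !purine] <- sub[valid & !purine]
  out[valid & purine] <- complement_substitution(sub[valid & purine])
  out
}

#' Summarize a somatic mutation table
#'
#' Tabulates variant classifications, variant types (SNP/DEL/INS) and
#' single-nucleotide substitution classes, plus per-sample mutation counts
#' and the most recurrently mutated genes. Substitutions with a purine
#' reference are collapsed onto the pyrimidine strand (G>A is counted as
#' C>T), the standard six-class convention. SNP records with multi-base or
#' non-ACGT alleles are excluded from the substitution-class counts only,
#' with a message.
#'
#' @param maf A mutation tibble (see [read_maf()]).
#' @param n_top Number of top mutated genes to report (ranked by the number
#'   of distinct mutated samples, ties broken alphabetically).
#' @return A list of class `variant_summary` with tibbles
#'   `by_classification`, `by_type`, `by_snv_class`, `per_sample` and
#'   `top_genes`.
#' @export
summarize_variants <- function(maf, n_top = 20) {
  validate_maf(maf)
  if (nrow(maf) == 0) stop("empty mutation table")

  by_classification <- maf |>
    dplyr::count(.data$variant_classification, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$variant_classification)

  by_type <- maf |>
    dplyr::count(.data$variant_type, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$variant_type)

  snp <- dplyr::filter(maf, .data$variant_type == "SNP")
  sub <- collapse_substitution(snp$ref_allele, snp$alt_allele)
  n_ambiguous <- sum(is.na(sub))
  if (n_ambiguous > 0) {
    message(sprintf(
      "%d SNP record(s) with ambiguous alleles excluded from substitution-class counts",
      n_ambiguous))
  }
  by_snv_class <- tibble::tibble(
    snv_class = snv_classes(),
    n = as.integer(table(factor(sub, levels = snv_classes())))
  )

  per_sample <- maf |>
    dplyr::count(.data$sample, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$sample)

  top_genes <- maf |>
    dplyr::distinct(.data$gene, .data$sample) |>
    dplyr::count(.data$gene, name = "n_mutated_samples") |>
    dplyr::arrange(dplyr::desc(.data$n_mutated_samples), .data$gene) |>
    dplyr::slice_head(n = n_top)

  structure(list(by_classification = by_classification, by_type = by_type,
                 by_snv_class = by_snv_class, per_sample = per_sample,
                 top_genes = top_genes),
            class = "variant_summary")
}

#' Compute per-sample tumor mutational burden
#'
#' TMB for a sample is the number of counted mutations divided by the size
#' in megabases of the interrogated exome. By default only the nine
#' nonsynonymous classes of [nonsynonymous_classes()] are counted.
#'
#' @param maf A mutation tibble.
#' @param exome_mb Exome size in megabases (default 38).
#' @param nonsyn_only Count only nonsynonymous classes (default `TRUE`).
#' @param samples Optional character vector of sample ids that must appear in
#'   the result; samples absent from the MAF get TMB 0 with a warning (set
#'   `missing_sample = "error"` to make that fatal).
#' @param missing_sample `"warn"` or `"error"` for samples without records.
#' @return Tibble with columns `sample`, `n_mutations`, `tmb`, ordered by
#'   `samples` when given.
#' @export
compute_tmb <- function(maf, exome_mb = 38, nonsyn_only = TRUE,
                        samples = NULL, missing_sample = c("warn", "error")) {
  validate_maf(maf)
  missing_sample <- match.arg(missing_sample)
  if (exome_mb <= 0) stop("exome_mb must be positive")
  counted <- if (nonsyn_only) {
    dplyr::filter(maf, .data$variant_classification %in% nonsynonymous_classes())
  } else maf
  if (is.null(samples)) samples <- sort(unique(maf$sample))
  absent <- setdiff(samples, unique(maf$sample))
  if (length(absent) > 0) {
    msg <- sprintf("%d sample(s) have no mutation records; TMB set to 0: %s",
                   length(absent),
                   paste(utils::head(absent, 5), collapse = ", "))
    if (missing_sample == "error") stop(msg) else warning(msg)
  }
  n <- table(factor(counted$sample, levels = samples))
  tibble::tibble(sample = samples,
                 n_mutations = as.integer(n),
                 tmb = as.numeric(n) / exome_mb)
}

#' Split samples into high/low TMB groups at the median
#'
#' Samples strictly above the median TMB are `"high"`; ties at the median go
#' to `"low"`.
#'
#' @param tmb Tibble with columns `sample` and `tmb` (from [compute_tmb()]).
#' @return The input with a `group` column added; the median is attached as
#'   attribute `median_tmb`.
#' @export
split_by_median <- function(tmb) {
  stopifnot(all(c("sample", "tmb") %in% colnames(tmb)), nrow(tmb) >= 2)
  med <- stats::median(tmb$tmb)
  if (all(tmb$tmb == tmb$tmb[1])) {
    stop("degenerate split: all samples have identical TMB")
  }
  out <- dplyr::mutate(tmb, group = ifelse(.data$tmb > med, "high", "low"))
  attr(out, "median_tmb") <- med
  out
}

#' Two-sided Fisher test for mutation co-occurrence
#'
#' Exact two-sided test on the 2x2 mutated/not-mutated contingency table of
#' two genes, with the conditional maximum-likelihood odds ratio.
#'
#' @param n_both Samples mutated in both genes.
#' @param n_only_a,n_only_b Samples mutated in exactly one gene.
#' @param n_neither Samples mutated in neither.
#' @return List with `p` and `odds_ratio` (possibly `Inf`).
#' @export
fisher_cooccurrence <- function(n_both, n_only_a, n_only_b, n_neither) {
  tab <- matrix(c(n_both, n_only_a, n_only_b, n_neither), nrow = 2)
  ft <- stats::fisher.test(tab)
  list(p = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Pairwise co-occurrence and mutual exclusivity of mutated genes
#'
#' For every pair among the `top_n` most recurrently mutated genes, builds
#' the 2x2 table of samples mutated in each gene and applies a two-sided
#' Fisher exact test. Pairs with odds ratio above 1 are labelled
#' co-occurrence, otherwise mutually exclusive. Both raw p-values and
#' Benjamini-Hochberg adjusted values across all pairs are reported.
#'
#' @param maf A mutation tibble.
#' @param top_n Number of top mutated genes to test pairwise (default 20).
#' @return Tibble with columns `gene_a`, `gene_b`, `n_both`, `n_only_a`,
#'   `n_only_b`, `n_neither`, `odds_ratio`, `p`, `q`, `label`.
#' @export
mutation_interactions <- function(maf, top_n = 20) {
  validate_maf(maf)
  vs <- suppressMessages(summarize_variants(maf, n_top = top_n))
  genes <- vs$top_genes$gene
  if (length(genes) < 2) stop("fewer than 2 genes among the top mutated genes")
  samples <- unique(maf$sample)
  mutated <- vapply(genes, function(g) {
    samples %in% maf$sample[maf$gene == g]
  }, logical(length(samples)))

  pairs <- utils::combn(seq_along(genes), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i <- pairs[1, j]; k <- pairs[2, j]
    a <- mutated[, i]; b <- mutated[, k]
    n_both <- sum(a & b); n_only_a <- sum(a & !b)
    n_only_b <- sum(!a & b); n_neither <- sum(!a & !b)
    ft <- fisher_cooccurrence(n_both, n_only_a, n_only_b, n_neither)
    tibble::tibble(
      gene_a = genes[i], gene_b = genes[k],
      n_both = n_both, n_only_a = n_only_a, n_only_b = n_only_b,
      n_neither = n_neither, odds_ratio = ft$odds_ratio, p = ft$p
    )
  })
  res |>
    dplyr::mutate(
      q = stats::p.adjust(.data$p, method = "BH"),
      label = ifelse(.data$odds_ratio > 1, "co-occurrence", "mutually_exclusive")
    )
}
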