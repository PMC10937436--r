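as_group_tbl <- function(groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(sample = names(groups), group = unname(groups))
  }
  groups
}

#' Gene-level differential methylation between tumor and normal samples
#'
#' A sample's gene-level beta is the unweighted mean over every probe mapped
#' to the gene (probes missing in a sample are skipped for that sample).
#' Group means are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param meth A `meth_set` (see [read_methylation()]).
#' @param gene Gene symbol; at least one mapped probe required.
#' @param groups Tibble with `sample` and `group` (levels `tumor` and
#'   `normal`), or a named vector.
#' @return A list of class `gene_methylation`: `gene`, `group_means` (tibble
#'   `group`, `mean_beta`, `n`), `p`, and `per_sample` (tibble `sample`,
#'   `group`, `beta`).
#' @export
gene_level_methylation <- function(meth, gene, groups) {
  stopifnot(inherits(meth, "meth_set"))
  groups <- as_group_tbl(groups)
  probes <- meth$probe_map$probe[meth$probe_map$gene == gene]
  probes <- intersect(probes, rownames(meth$beta))
  if (length(probes) == 0) stop("no probes mapped to gene '", gene, "'")
  gene_beta <- colMeans(meth$beta[probes, , drop = FALSE], na.rm = TRUE)
  per_sample <- tibble::tibble(sample = names(gene_beta), beta = gene_beta) |>
    dplyr::inner_join(groups, by = "sample")
  lev <- intersect(c("tumor", "normal"), unique(per_sample$group))
  if (length(lev) < 2) stop("both tumor and normal groups must be non-empty")
  x <- per_sample$beta[per_sample$group == "tumor"]
  y <- per_sample$beta[per_sample$group == "normal"]
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  structure(list(
    gene = gene,
    group_means = tibble::tibble(group = c("tumor", "normal"),
                                 mean_beta = c(mean(x), mean(y)),
                                 n = c(length(x), length(y))),
    p = p,
    per_sample = dplyr::select(per_sample, "sample", "group", "beta")
  ), class = "gene_methylation")
}

#' @export
print.gene_methylation <- function(x, ...) {
  cat(sprintf("gene-level methylation of %s: tumor %.3f vs normal %.3f (p = %.3g)\n",
              x$gene, x$group_means$mean_beta[1], x$group_means$mean_beta[2],
              x$p))
  invisible(x)
}

#' Per-probe differential methylation between tumor and normal samples
#'
#' Two-sided Wilcoxon rank-sum test per probe with Benjamini-Hochberg
#' adjustment across probes. A probe is `hyper` when its tumor mean beta
#' exceeds the normal mean, `hypo` otherwise. Probes entirely missing in
#' either group are skipped with a message.
#'
#' @param meth A `meth_set`.
#' @param groups Tibble with `sample` and `group` (levels `tumor`, `normal`).
#' @return Tibble with columns `probe`, `delta_beta` (tumor minus normal
#'   mean), `p`, `fdr`, `status`.
#' @export
site_differential_methylation <- function(meth, groups) {
  stopifnot(inherits(meth, "meth_set"))
  groups <- as_group_tbl(groups)
  tumor <- intersect(groups$sample[groups$group == "tumor"], colnames(meth$beta))
  normal <- intersect(groups$sample[groups$group == "normal"], colnames(meth$beta))
  if (length(tumor) < 3 || length(normal) < 3) {
    stop("need at least 3 tumor and 3 normal samples")
  }
  rows <- purrr::map_dfr(rownames(meth$beta), function(pr) {
    x <- meth$beta[pr, tumor]; y <- meth$beta[pr, normal]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      message("probe ", pr, " entirely missing in one group; skipped")
      return(NULL)
    }
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    tibble::tibble(probe = pr, delta_beta = mean(x) - mean(y), p = p)
  })
  rows |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p, method = "BH"),
                  status = ifelse(.data$delta_beta > 0, "hyper", "hypo"))
}

#' Correlation between probe methylation and a gene's expression
#'
#' Pearson (default) or Spearman correlation between each probe's beta
#' values and the target gene's expression over the paired samples, with
#' two-sided p-values. Probes with fewer than 10 paired observations are
#' skipped; constant probes yield a missing correlation with a warning.
#'
#' @param meth A `meth_set`.
#' @param expr Gene x sample expression matrix.
#' @param gene Target gene symbol (must be in `expr`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param probes Optional probe subset; defaults to the probes mapped to
#'   `gene`, or every probe if none is mapped.
#' @return Tibble with columns `probe`, `cor`, `p`, `n`.
#' @export
site_expression_correlation <- function(meth, expr, gene,
                                        method = c("pearson", "spearman"),
                                        probes = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(meth, "meth_set"), is.matrix(expr))
  if (!gene %in% rownames(expr)) stop("gene '", gene, "' not in expression matrix")
  if (is.null(probes)) {
    probes <- meth$probe_map$probe[meth$probe_map$gene == gene]
    if (length(probes) == 0) probes <- rownames(meth$beta)
  }
  probes <- intersect(probes, rownames(meth$beta))
  shared <- intersect(colnames(meth$beta), colnames(expr))
  e <- expr[gene, shared]
  purrr::map_dfr(probes, function(pr) {
    b <- meth$beta[pr, shared]
    ok <- !is.na(b)
    if (sum(ok) < 10) {
      message("probe ", pr, " has fewer than 10 paired samples; skipped")
      return(NULL)
    }
    if (stats::sd(b[ok]) == 0) {
      warning("probe ", pr, " has constant beta; correlation undefined")
      return(tibble::tibble(probe = pr, cor = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(b[ok], e[ok], method = method))
    tibble::tibble(probe = pr, cor = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok))
  })
}
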