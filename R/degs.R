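# Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction, matching stats::wilcox.test with
# exact = FALSE, correct = TRUE). Returns one p-value per matrix row.
rank_sum_p <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  apply(mat[, c(idx1, idx2), drop = FALSE], 1, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nties <- table(r)
    z <- w - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n1 + n2 + 1) -
                       sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1))))
    if (sigma == 0) return(1)
    z <- (z - sign(z) * 0.5) / sigma
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test (normal approximation with tie
#' and continuity corrections) with Benjamini-Hochberg adjustment across
#' genes. The log fold change is the difference in group means on the log2
#' scale, first level minus second level; a gene is called a DEG when its
#' FDR falls below `fdr_threshold` and `|log_fc|` reaches `logfc_threshold`
#' (0 by default, i.e. the FDR rule alone decides).
#'
#' @param expr Gene x sample expression matrix (log2 scale).
#' @param groups Tibble with `sample` and `group`, or a named character
#'   vector; exactly two levels. The first level (factor order, else sorted
#'   order) is the reference for the sign of `log_fc`.
#' @param method Test engine; only `"wilcoxon"` is currently implemented.
#' @param fdr_threshold BH FDR threshold for the DEG call (default 0.05).
#' @param logfc_threshold Minimum absolute log2 fold change (default 0).
#' @return Tibble with columns `gene`, `log_fc`, `p`, `fdr`, `direction`
#'   (`up` = higher in the first level) and `deg`.
#' @export
differential_expression <- function(expr, groups, method = "wilcoxon",
                                    fdr_threshold = 0.05,
                                    logfc_threshold = 0) {
  method <- match.arg(method, "wilcoxon")
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(sample = names(groups), group = unname(groups))
  }
  groups <- dplyr::filter(groups, .data$sample %in% colnames(expr))
  levels <- if (is.factor(groups$group)) levels(droplevels(groups$group))
            else sort(unique(as.character(groups$group)))
  if (length(levels) != 2) {
    stop("need exactly 2 groups, found: ", paste(levels, collapse = ", "))
  }
  idx1 <- match(groups$sample[groups$group == levels[1]], colnames(expr))
  idx2 <- match(groups$sample[groups$group == levels[2]], colnames(expr))
  if (length(idx1) < 3 || length(idx2) < 3) {
    stop("need at least 3 samples per group")
  }
  p <- rank_sum_p(expr, idx1, idx2)
  log_fc <- rowMeans(expr[, idx1, drop = FALSE]) -
    rowMeans(expr[, idx2, drop = FALSE])
  fdr <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene = rownames(expr),
    log_fc = unname(log_fc),
    p = unname(p),
    fdr = unname(fdr),
    direction = ifelse(log_fc >= 0, "up", "down"),
    deg = fdr < fdr_threshold & abs(log_fc) >= logfc_threshold
  )
}

#' Intersect named DEG sets
#'
#' Computes the genes common to every set plus Venn-style region counts
#' (one count per membership pattern).
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return A list of class `deg_intersection` with `common` (character),
#'   `membership` (tibble: gene plus one logical column per set) and
#'   `region_counts` (tibble `pattern`, `n`).
#' @export
intersect_deg_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  if (any(lengths(sets) == 0)) {
    warning("empty DEG set(s): ",
            paste(names(sets)[lengths(sets) == 0], collapse = ", "),
            "; intersection is empty")
  }
  all_genes <- sort(unique(unlist(sets)))
  membership <- tibble::tibble(gene = all_genes)
  for (nm in names(sets)) membership[[nm]] <- all_genes %in% sets[[nm]]
  pattern <- apply(membership[-1], 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  region_counts <- tibble::tibble(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::arrange(.data$pattern)
  common <- all_genes[rowSums(as.matrix(membership[-1])) == length(sets)]
  structure(list(common = common, membership = membership,
                 region_counts = region_counts),
            class = "deg_intersection")
}

#' @export
print.deg_intersection <- function(x, ...) {
  cat(sprintf("DEG intersection over %d sets: %d common gene(s)\n",
              ncol(x$membership) - 1, length(x$common)))
  print(x$region_counts)
  invisible(x)
}

#' Restrict a DEG table to immune-related genes
#'
#' @param deg A DEG tibble from [differential_expression()].
#' @param immune_genes Character vector of immune gene symbols.
#' @return Character vector: DEG-flagged genes that are immune-related.
#' @export
select_immune_degs <- function(deg, immune_genes) {
  intersect(deg$gene[deg$deg], immune_genes)
}
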