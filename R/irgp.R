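#' Build the binary immune gene-pair indicator matrix
#'
#' For every unordered pair of immune genes present in the expression matrix,
#' the pair indicator for a sample is 1 if the first gene's expression
#' strictly exceeds the second's and 0 otherwise (ties score 0). Pairs are
#' canonically ordered with `gene_a` lexicographically before `gene_b`.
#' Because the indicator depends only on the within-sample ordering of two
#' genes, the matrix is invariant under any strictly increasing transform of
#' the expression values — the property that lets a pair signature transfer
#' across platforms without renormalization.
#'
#' @param expr Gene x sample numeric expression matrix.
#' @param immune_genes Character vector of immune-related gene symbols; only
#'   genes present in `expr` are paired.
#' @return An object of class `irgp_matrix`: a list with `s` (pair x sample
#'   binary matrix, rownames `"GENEA|GENEB"`) and `pairs` (tibble `pair_id`,
#'   `gene_a`, `gene_b`).
#' @export
build_pair_matrix <- function(expr, immune_genes) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  present <- sort(intersect(unique(immune_genes), rownames(expr)))
  if (length(present) < 2) {
    stop("fewer than 2 immune genes found in the expression matrix")
  }
  idx <- utils::combn(length(present), 2)
  ga <- present[idx[1, ]]
  gb <- present[idx[2, ]]
  sub <- expr[present, , drop = FALSE]
  s <- (sub[idx[1, ], , drop = FALSE] > sub[idx[2, ], , drop = FALSE]) * 1
  rownames(s) <- paste(ga, gb, sep = "|")
  structure(list(
    s = s,
    pairs = tibble::tibble(pair_id = rownames(s), gene_a = ga, gene_b = gb)
  ), class = "irgp_matrix")
}

#' Filter gene pairs by indicator balance
#'
#' Retains pairs whose indicator frequency `f = mean(s)` lies in
#' `[min_freq, 1 - min_freq]`. Pairs that are (almost) always 0 or always 1
#' carry no discriminating information; the balance band keeps the pairs
#' whose ordering actually varies across the cohort.
#'
#' @param ipm An `irgp_matrix` from [build_pair_matrix()].
#' @param min_freq Lower bound of the balance band, in (0, 0.5).
#' @return A filtered `irgp_matrix`; the per-pair frequencies of the retained
#'   pairs are attached as attribute `pair_freq`.
#' @export
filter_pairs <- function(ipm, min_freq = 0.2) {
  stopifnot(inherits(ipm, "irgp_matrix"), min_freq > 0, min_freq < 0.5)
  f <- rowMeans(ipm$s)
  keep <- f >= min_freq & f <= 1 - min_freq
  if (!any(keep)) {
    hist <- table(cut(f, breaks = seq(0, 1, 0.1), include.lowest = TRUE))
    stop("no pair survives the balance filter [", min_freq, ", ",
         1 - min_freq, "]; frequency histogram: ",
         paste(names(hist), hist, sep = "=", collapse = ", "))
  }
  message(sprintf("retained %d of %d pairs in balance band [%g, %g]",
                  sum(keep), length(f), min_freq, 1 - min_freq))
  out <- structure(list(
    s = ipm$s[keep, , drop = FALSE],
    pairs = ipm$pairs[keep, , drop = FALSE]
  ), class = "irgp_matrix")
  attr(out, "pair_freq") <- f[keep]
  out
}

#' Check monotone invariance of the pair indicator construction
#'
#' Applies a strictly increasing transform to the expression values and
#' verifies that the pair indicator matrix is unchanged — the design
#' guarantee of rank-based pair scoring.
#'
#' @param expr Gene x sample expression matrix.
#' @param immune_genes Immune gene symbols to pair.
#' @param transform A strictly increasing function applied to the expression
#'   values (default `exp`).
#' @return A list of class `invariance_check` with `identical` (logical) and
#'   `n_differing` (entry count).
#' @export
check_monotone_invariance <- function(expr, immune_genes, transform = exp) {
  m1 <- build_pair_matrix(expr, immune_genes)
  transformed <- expr
  transformed[] <- transform(expr)
  m2 <- build_pair_matrix(transformed, immune_genes)
  n_diff <- sum(m1$s != m2$s)
  structure(list(identical = n_diff == 0, n_differing = n_diff),
            class = "invariance_check")
}

#' Write a pair indicator matrix to TSV
#' @param ipm An `irgp_matrix`.
#' @param path Output path; first column `pair_id`, one column per sample.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(ipm, path) {
  stopifnot(inherits(ipm, "irgp_matrix"))
  out <- tibble::as_tibble(ipm$s, rownames = "pair_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.irgp_matrix <- function(x, ...) {
  f <- rowMeans(x$s)
  cat(sprintf("IRGP indicator matrix: %d pairs x %d samples\n",
              nrow(x$s), ncol(x$s)))
  cat(sprintf("indicator frequency: min %.3f, median %.3f, max %.3f\n",
              min(f), stats::median(f), max(f)))
  invisible(x)
}

#' @export
print.invariance_check <- function(x, ...) {
  cat(if (x$identical) "pair matrix invariant under the transform\n"
      else sprintf("pair matrix NOT invariant: %d differing entries\n",
                   x$n_differing))
  invisible(x)
}

#' @method tidy irgp_matrix
#' @export
tidy.irgp_matrix <- function(x, ...) {
  dplyr::mutate(x$pairs, frequency = rowMeans(x$s))
}
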