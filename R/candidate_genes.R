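#' Per-gene prognostic evaluation
#'
#' For each gene: a univariate Cox fit on its continuous expression (hazard
#' ratio per unit of log2 expression), a joint multivariate Cox fit over all
#' requested genes, and a log-rank comparison of the median-split high/low
#' expression groups (ties at the median join the low group). Genes absent
#' from the expression matrix are reported in the `absent` attribute rather
#' than failing.
#'
#' @param expr Gene x sample expression matrix.
#' @param clinical Clinical tibble.
#' @param genes Character vector of gene symbols to evaluate.
#' @return Tibble with columns `gene`, `hr`, `ci_low`, `ci_high`,
#'   `p_univariate`, `p_multivariate`, `km_logrank_p`.
#' @export
gene_cox_table <- function(expr, clinical, genes) {
  stopifnot(is.matrix(expr))
  validate_clinical(clinical)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    message("gene(s) absent from expression matrix: ",
            paste(absent, collapse = ", "))
  }
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) stop("none of the requested genes are present")
  al <- align_features_clinical(expr[genes, , drop = FALSE], clinical)
  x <- al$x; clinical <- al$clinical
  y <- survival::Surv(clinical$os_time, clinical$os_event)

  uni <- purrr::map_dfr(genes, function(g) {
    v <- x[g, ]
    fit <- suppressWarnings(survival::coxph(y ~ v))
    dplyr::mutate(cox_tidy(fit), term = g)
  })

  df <- as.data.frame(t(x))
  safe <- paste0("g", seq_along(genes))
  names(df) <- safe
  multi <- if (length(genes) >= 2) {
    fit <- suppressWarnings(survival::coxph(
      stats::as.formula(paste("y ~", paste(safe, collapse = " + "))),
      data = df))
    stats::setNames(cox_tidy(fit)$p, genes)
  } else stats::setNames(uni$p, genes)

  km_p <- vapply(genes, function(g) {
    v <- x[g, ]
    med <- stats::median(v)
    if (all(v <= med)) {
      warning("degenerate median split for gene ", g)
      return(NA_real_)
    }
    grp <- tibble::tibble(sample = clinical$sample,
                          group = ifelse(v > med, "high", "low"))
    compare_groups(grp, clinical)$p
  }, 0)

  tibble::tibble(
    gene = genes,
    hr = uni$hr, ci_low = uni$ci_low, ci_high = uni$ci_high,
    p_univariate = uni$p,
    p_multivariate = unname(multi[genes]),
    km_logrank_p = unname(km_p)
  ) -> out
  attr(out, "absent") <- absent
  out
}

#' Rank candidate genes by penalized Cox coefficients
#'
#' Standardizes each gene's expression, fits a lasso Cox model with the
#' penalty chosen by cross-validated partial-likelihood deviance (minimum
#' rule), and ranks genes by absolute coefficient at that penalty. The
#' top-ranked gene is the key gene. Duplicated expression rows are collapsed
#' first so the L1 solution is unique over the retained genes.
#'
#' @param expr Gene x sample expression matrix.
#' @param clinical Clinical tibble.
#' @param genes Genes to rank (at least 2 present in `expr`).
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Tibble with columns `gene`, `coefficient`, `rank`, sorted by rank;
#'   empty (with a message and a `diagnostic` attribute) if every
#'   coefficient is zero at the chosen penalty.
#' @export
prioritize_genes <- function(expr, clinical, genes, nfolds = 10, seed = 1L) {
  stopifnot(is.matrix(expr))
  validate_clinical(clinical)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) stop("need at least 2 genes present in the matrix")
  x <- expr[genes, , drop = FALSE]
  dup <- duplicated(as.data.frame(x))
  if (any(dup)) {
    message(sprintf("collapsed %d duplicated gene row(s), keeping the first", sum(dup)))
    x <- x[!dup, , drop = FALSE]
    genes <- genes[!dup]
  }
  al <- align_features_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  xs <- t(scale(t(x)))  # standardize per gene
  y <- survival::Surv(clinical$os_time, clinical$os_event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = ncol(xs)))
  cv <- glmnet::cv.glmnet(t(xs), y, family = "cox", foldid = foldid,
                          standardize = FALSE)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  nz <- beta[beta != 0]
  if (length(nz) == 0) {
    message("all coefficients zero at the cross-validated penalty")
    out <- tibble::tibble(gene = character(), coefficient = numeric(),
                          rank = integer())
    attr(out, "diagnostic") <- list(lambda_min = cv$lambda.min,
                                    cvm_min = min(cv$cvm))
    return(out)
  }
  ord <- order(abs(nz), decreasing = TRUE)
  tibble::tibble(gene = names(nz)[ord], coefficient = unname(nz[ord]),
                 rank = seq_along(ord))
}

#' Pairwise correlations between candidate genes
#'
#' Spearman (default) or Pearson correlation for every gene pair, with
#' two-sided p-values. Constant genes yield missing correlations with a
#' warning.
#'
#' @param expr Gene x sample expression matrix.
#' @param genes Genes to correlate (at least 2 present, at least 10 samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list of class `gene_cor`: `correlations` (tibble `gene_a`,
#'   `gene_b`, `estimate`, `p`), `matrix` (symmetric estimate matrix with
#'   unit diagonal) and `method`.
#' @export
gene_correlations <- function(expr, genes, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr))
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) stop("need at least 2 genes present in the matrix")
  if (ncol(expr) < 10) stop("need at least 10 samples")
  est <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  diag(est) <- 1
  rows <- list()
  for (i in seq_len(length(genes) - 1)) {
    for (j in seq(i + 1, length(genes))) {
      vi <- expr[genes[i], ]; vj <- expr[genes[j], ]
      if (stats::sd(vi) == 0 || stats::sd(vj) == 0) {
        warning("constant gene in pair ", genes[i], "-", genes[j],
                "; correlation undefined")
        ct <- list(estimate = NA_real_, p.value = NA_real_)
      } else {
        ct <- suppressWarnings(stats::cor.test(vi, vj, method = method))
      }
      est[i, j] <- est[j, i] <- unname(ct$estimate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_a = genes[i], gene_b = genes[j],
        estimate = unname(ct$estimate), p = ct$p.value)
    }
  }
  structure(list(correlations = dplyr::bind_rows(rows), matrix = est,
                 method = method),
            class = "gene_cor")
}

#' @export
print.gene_cor <- function(x, ...) {
  cat(sprintf("pairwise %s correlations for %d genes\n", x$method,
              nrow(x$matrix)))
  print(x$correlations)
  invisible(x)
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Computes, per sample, delta-Ct (target minus reference cycle threshold),
#' delta-delta-Ct against the calibrator sample, and the fold change
#' `2^-ddCt`. Replicate rows for the same sample are averaged before the
#' delta step. The calibrator's fold change is 1 by construction, and
#' adding a constant to both target and reference Cts leaves fold changes
#' unchanged.
#'
#' @param ct Tibble with columns `sample`, `ct_target`, `ct_reference`
#'   (cycle numbers, each in (0, 45)); one or more rows per sample.
#' @param calibrator Sample id used as the calibrator.
#' @return Tibble with columns `sample`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(ct, calibrator) {
  stopifnot(all(c("sample", "ct_target", "ct_reference") %in% colnames(ct)))
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(vals <= 0 | vals >= 45)) stop("Ct values must lie in (0, 45)")
  agg <- ct |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ct_target = mean(.data$ct_target),
                     ct_reference = mean(.data$ct_reference),
                     .groups = "drop") |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_reference)
  if (!calibrator %in% agg$sample) {
    stop("calibrator sample '", calibrator, "' not found")
  }
  cal_dct <- agg$delta_ct[agg$sample == calibrator]
  agg |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct - cal_dct,
                  fold_change = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("sample", "delta_ct", "delta_delta_ct", "fold_change")
}
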