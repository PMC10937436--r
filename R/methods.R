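#' @export
print.irgp_model <- function(x, ...) {
  cat(sprintf("pair-based prognostic model (%s): %d pairs\n",
              x$method, nrow(x$pairs)))
  if (!is.na(x$cutoff)) {
    cat(sprintf("risk cutoff %.4f, training AUC %.3f\n", x$cutoff,
                x$training_auc))
  }
  print(x$pairs)
  invisible(x)
}

#' @rdname fit_model
#' @param x An `irgp_model`.
#' @param ... Unused.
#' @method tidy irgp_model
#' @export
tidy.irgp_model <- function(x, ...) x$pairs

#' @rdname fit_model
#' @method glance irgp_model
#' @export
glance.irgp_model <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), method = x$method,
                 lambda = x$lambda, cutoff = x$cutoff,
                 training_auc = x$training_auc)
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("survival ROC at %d days: AUC %.3f, Youden cutoff %.4f\n",
              x$horizon_days, x$auc, x$cutoff))
  cat(sprintf("%d labelled samples (%d censored before horizon excluded)\n",
              x$n_used, x$n_excluded))
  invisible(x)
}

#' @rdname optimal_cutoff
#' @param x A `cutoff_result`.
#' @param ... Unused.
#' @method tidy cutoff_result
#' @export
tidy.cutoff_result <- function(x, ...) x$roc

#' @rdname optimal_cutoff
#' @method glance cutoff_result
#' @export
glance.cutoff_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff, horizon_days = x$horizon_days,
                 n_used = x$n_used, n_excluded = x$n_excluded)
}

#' @rdname optimal_cutoff
#' @param object A `cutoff_result`.
#' @method autoplot cutoff_result
#' @export
autoplot.cutoff_result <- function(object, ...) {
  pts <- dplyr::arrange(object$roc, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("survival ROC at %d days (AUC %.3f)",
                      object$horizon_days, object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  print(x$n_per_group)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @method tidy survival_comparison
#' @export
tidy.survival_comparison <- function(x, ...) x$km

#' @rdname compare_groups
#' @method glance survival_comparison
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p = x$p)
}

#' @rdname compare_groups
#' @param object A `survival_comparison`.
#' @method autoplot survival_comparison
#' @export
autoplot.survival_comparison <- function(object, ...) {
  ggplot2::ggplot(object$km,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival fraction",
                  colour = "group",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' @rdname fit_model
#' @param object An `irgp_model`.
#' @method autoplot irgp_model
#' @export
autoplot.irgp_model <- function(object, ...) {
  pairs <- dplyr::mutate(object$pairs,
                         pair_id = stats::reorder(.data$pair_id,
                                                  .data$coefficient))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$coefficient,
                                      y = .data$pair_id)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$coefficient,
                                       yend = .data$pair_id),
                          colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cox coefficient", y = NULL,
                  title = "selected prognostic gene pairs") +
    ggplot2::theme_minimal()
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("variant classification counts:\n")
  print(x$by_classification)
  cat("variant types:\n")
  print(x$by_type)
  cat("substitution classes (pyrimidine strand):\n")
  print(x$by_snv_class)
  invisible(x)
}

#' @rdname summarize_variants
#' @param x A `variant_summary`.
#' @param ... Unused.
#' @method tidy variant_summary
#' @export
tidy.variant_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$by_classification,
                                level = "variant_classification"),
                  facet = "classification"),
    dplyr::mutate(dplyr::rename(x$by_type, level = "variant_type"),
                  facet = "type"),
    dplyr::mutate(dplyr::rename(x$by_snv_class, level = "snv_class"),
                  facet = "snv_class"))
}

#' @rdname summarize_variants
#' @param object A `variant_summary`.
#' @method autoplot variant_summary
#' @export
autoplot.variant_summary <- function(object, ...) {
  dat <- tidy.variant_summary(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n,
                                    y = stats::reorder(.data$level, .data$n))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~facet, scales = "free") +
    ggplot2::labs(x = "records", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("synthetic cohort spec: %d samples x %d genes (%d immune)\n",
              x$n_samples, x$n_genes, length(x$immune_genes)))
  cat(sprintf("%d driver pair(s), tmb_beta %.3f, seed %d\n",
              nrow(x$driver_pairs), x$tmb_beta, x$seed))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples, %d mutation records\n",
              nrow(x$expression), ncol(x$expression), nrow(x$maf)))
  cat(sprintf("%d events / %d samples; %d methylation probes\n",
              sum(x$clinical$os_event), nrow(x$clinical),
              nrow(x$methylation$beta)))
  invisible(x)
}

#' @export
print.independence_result <- function(x, ...) {
  cat("univariate Cox fits:\n")
  print(x$univariate)
  cat("multivariate Cox fit:\n")
  print(x$multivariate)
  invisible(x)
}

#' Volcano-style plot of a differential-expression table
#'
#' @param deg A DEG tibble from [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg) {
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$log_fc, y = -log10(.data$p),
                                    colour = .data$deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "DEG") +
    ggplot2::theme_minimal()
}
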