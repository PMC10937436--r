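as_feature_matrix <- function(features) {
  if (inherits(features, "irgp_matrix")) return(features$s)
  if (is.matrix(features)) {
    stopifnot(!is.null(rownames(features)), !is.null(colnames(features)))
    return(features)
  }
  stop("features must be an irgp_matrix or a feature x sample numeric matrix")
}

cox_tidy <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"])
  )
}

align_features_clinical <- function(x, clinical) {
  keep <- intersect(colnames(x), clinical$sample)
  if (length(keep) == 0) stop("no samples shared between features and clinical table")
  n_drop <- length(union(colnames(x), clinical$sample)) - length(keep)
  if (n_drop > 0) {
    message(sprintf("dropping %d sample(s) absent from features or clinical table", n_drop))
  }
  list(x = x[, keep, drop = FALSE],
       clinical = clinical[match(keep, clinical$sample), ])
}

#' Univariate Cox screening of candidate features
#'
#' Fits a univariate proportional-hazards model per feature and retains those
#' below the p-value threshold. The score (log-rank) test p-value is used for
#' screening because it remains informative when a binary feature separates
#' the risk sets; hazard ratios come from the partial-likelihood estimate.
#' Constant features are skipped with a warning rather than an error.
#'
#' @param features An `irgp_matrix` or a feature x sample numeric matrix.
#' @param clinical Clinical tibble with `sample`, `os_time`, `os_event`.
#' @param p_threshold Retention threshold on the score-test p-value
#'   (default 0.01). The threshold trades the false-positive load handed to
#'   the penalized fit against the retention of true effects whose marginal
#'   (univariate) hazard ratios are attenuated by the other prognostic
#'   features acting as unmodelled frailty; at a candidate universe of a few
#'   thousand pairs, 0.01 keeps that load to a few dozen while retaining
#'   moderately sized true effects.
#' @return Tibble with columns `feature`, `hr`, `ci_low`, `ci_high`, `p` and
#'   `keep`; skipped constant features are recorded in attribute `skipped`.
#' @export
univariate_screen <- function(features, clinical, p_threshold = 0.01) {
  x <- as_feature_matrix(features)
  validate_clinical(clinical)
  al <- align_features_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  if (sum(clinical$os_event) < 10) stop("fewer than 10 events in the cohort")

  y <- survival::Surv(clinical$os_time, clinical$os_event)
  constant <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warning(sprintf("%d constant feature(s) skipped", sum(constant)))
  }
  rows <- purrr::map_dfr(which(!constant), function(i) {
    v <- x[i, ]
    fit <- suppressWarnings(survival::coxph(y ~ v))
    s <- suppressWarnings(summary(fit))
    tibble::tibble(
      feature = rownames(x)[i],
      hr = unname(s$coefficients[1, "exp(coef)"]),
      ci_low = unname(s$conf.int[1, "lower .95"]),
      ci_high = unname(s$conf.int[1, "upper .95"]),
      p = unname(s$sctest["pvalue"])
    )
  })
  rows <- dplyr::mutate(rows, keep = .data$p < p_threshold)
  attr(rows, "skipped") <- rownames(x)[constant]
  attr(rows, "p_threshold") <- p_threshold
  rows
}

#' Fit the penalized pair-based prognostic model
#'
#' Fits a penalized Cox proportional-hazards model over the candidate
#' features. The default is the lasso with the penalty chosen by 10-fold
#' cross-validated partial-likelihood deviance at its minimum; features with
#' nonzero coefficients at that penalty become the model's selected pairs.
#' Exactly duplicated feature rows are collapsed beforehand (keeping the
#' first) so the L1 solution is unique over the retained set. A classical
#' backward-stepwise Cox fit is available as `method = "stepwise"`.
#'
#' @param features An `irgp_matrix` or a feature x sample numeric matrix,
#'   already restricted to the screened candidates.
#' @param clinical Clinical tibble.
#' @param method `"lasso"` (default) or `"stepwise"`.
#' @param nfolds Cross-validation folds for the lasso penalty path.
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `irgp_model`: list with `pairs` (tibble
#'   `pair_id`, `gene_a`, `gene_b`, `coefficient`), `method`, `lambda`,
#'   `nfolds`, `seed`, `cutoff` and `training_auc` (both `NA` until set).
#' @export
fit_model <- function(features, clinical, method = c("lasso", "stepwise"),
                      nfolds = 10, seed = 1L) {
  method <- match.arg(method)
  x <- as_feature_matrix(features)
  validate_clinical(clinical)
  if (nrow(x) < 2) stop("need at least 2 candidate features")
  dup <- duplicated(as.data.frame(x))
  if (any(dup)) {
    message(sprintf("collapsed %d duplicated feature row(s), keeping the first", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  al <- align_features_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  y <- survival::Surv(clinical$os_time, clinical$os_event)

  if (method == "lasso") {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = ncol(x)))
    cv <- glmnet::cv.glmnet(t(x), y, family = "cox", foldid = foldid)
    beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
    lambda <- cv$lambda.min
  } else {
    df <- as.data.frame(t(x))
    safe <- paste0("f", seq_len(ncol(df)))
    names(df) <- safe
    df$.time <- clinical$os_time; df$.event <- clinical$os_event
    full <- survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~",
                              paste(safe, collapse = " + "))),
      data = df)
    red <- stats::step(full, direction = "backward", trace = 0)
    beta <- stats::setNames(rep(0, nrow(x)), safe)
    beta[names(stats::coef(red))] <- stats::coef(red)
    names(beta) <- rownames(x)
    lambda <- NA_real_
  }
  sel <- which(beta != 0)
  if (length(sel) == 0) {
    stop("no feature retained by the ", method,
         " fit; consider relaxing the screening threshold")
  }
  ids <- rownames(x)[sel]
  split_ids <- strsplit(ids, "|", fixed = TRUE)
  model <- structure(list(
    pairs = tibble::tibble(
      pair_id = ids,
      gene_a = vapply(split_ids, function(p) if (length(p) == 2) p[1] else NA_character_, ""),
      gene_b = vapply(split_ids, function(p) if (length(p) == 2) p[2] else NA_character_, ""),
      coefficient = unname(beta[sel])
    ),
    method = method, lambda = lambda, nfolds = nfolds, seed = as.integer(seed),
    cutoff = NA_real_, training_auc = NA_real_
  ), class = "irgp_model")
  model
}

#' Record the chosen risk cutoff on a fitted model
#'
#' @param model An `irgp_model`.
#' @param cutoff_result A `cutoff_result` from [optimal_cutoff()].
#' @return The model with `cutoff` and `training_auc` filled in.
#' @export
set_model_cutoff <- function(model, cutoff_result) {
  stopifnot(inherits(model, "irgp_model"), inherits(cutoff_result, "cutoff_result"))
  model$cutoff <- cutoff_result$cutoff
  model$training_auc <- cutoff_result$auc
  model
}

#' Compute per-sample risk scores
#'
#' The risk score is the coefficient-weighted sum of the model's pair
#' indicators. When `data` is an expression matrix the indicators are
#' recomputed directly from the gene pair orderings, so a validation cohort
#' needs no renormalization; when it is an `irgp_matrix` the stored rows are
#' used. At least 90% of the model's pairs must be computable, otherwise an
#' error lists what is missing.
#'
#' @param model An `irgp_model`.
#' @param data A gene x sample expression matrix or an `irgp_matrix`.
#' @return Tibble with columns `sample` and `risk_score`; pairs that could
#'   not be computed are attached as attribute `missing_pairs`.
#' @export
score_samples <- function(model, data) {
  stopifnot(inherits(model, "irgp_model"))
  pairs <- model$pairs
  if (inherits(data, "irgp_matrix")) {
    found <- pairs$pair_id %in% rownames(data$s)
    s <- data$s[pairs$pair_id[found], , drop = FALSE]
    samples <- colnames(data$s)
  } else {
    x <- data
    stopifnot(is.matrix(x), !is.null(rownames(x)))
    found <- pairs$gene_a %in% rownames(x) & pairs$gene_b %in% rownames(x)
    s <- (x[pairs$gene_a[found], , drop = FALSE] >
            x[pairs$gene_b[found], , drop = FALSE]) * 1
    samples <- colnames(x)
  }
  if (mean(found) < 0.9) {
    stop("only ", sum(found), "/", nrow(pairs),
         " model pairs computable (< 90% coverage); missing: ",
         paste(utils::head(pairs$pair_id[!found], 10), collapse = ", "))
  }
  if (any(!found)) {
    message(sprintf("%d model pair(s) not computable and skipped", sum(!found)))
  }
  score <- as.numeric(crossprod(s, pairs$coefficient[found]))
  out <- tibble::tibble(sample = samples, risk_score = score)
  attr(out, "missing_pairs") <- pairs$pair_id[!found]
  out
}

horizon_labels <- function(scores, clinical, horizon_days) {
  merged <- dplyr::inner_join(scores, clinical, by = "sample")
  dead <- merged$os_event == 1 & merged$os_time <= horizon_days
  alive <- merged$os_time > horizon_days
  usable <- dead | alive
  list(score = merged$risk_score[usable],
       label = as.numeric(dead[usable]),
       n_excluded = sum(!usable))
}

#' Choose the optimal risk cutoff from a fixed-horizon ROC curve
#'
#' Labels each sample by death before the horizon (patients censored before
#' the horizon are excluded from labelling), computes the ROC curve of the
#' risk score against that label, the trapezoidal AUC, and the cutoff
#' maximizing the Youden index J = sensitivity + specificity - 1. Candidate
#' cutoffs are the midpoints between consecutive distinct scores; ties in J
#' resolve to the lower cutoff. A sample is called high risk when its score
#' is strictly above the cutoff.
#'
#' @param scores Tibble with `sample` and `risk_score` (from
#'   [score_samples()]).
#' @param clinical Clinical tibble.
#' @param horizon_days Survival horizon in days (default 1825 = 5 years).
#' @return An object of class `cutoff_result`: list with `cutoff`, `auc`,
#'   `roc` (tibble `threshold`, `tpr`, `fpr`, `youden`), `n_used`,
#'   `n_excluded`, `horizon_days`.
#' @export
optimal_cutoff <- function(scores, clinical, horizon_days = 1825) {
  validate_clinical(clinical)
  hl <- horizon_labels(scores, clinical, horizon_days)
  if (length(unique(hl$label)) < 2) {
    stop("only one outcome class present at the ", horizon_days, "-day horizon")
  }
  sorted <- sort(unique(hl$score))
  if (length(sorted) < 2) stop("risk scores are constant; no cutoff exists")
  thresholds <- (sorted[-1] + sorted[-length(sorted)]) / 2
  pos <- hl$score[hl$label == 1]
  neg <- hl$score[hl$label == 0]
  tpr <- vapply(thresholds, function(c) mean(pos > c), 0)
  fpr <- vapply(thresholds, function(c) mean(neg > c), 0)
  youden <- tpr - fpr
  # lowest threshold within numerical tolerance of the maximum, so the
  # documented tie rule is robust to floating-point noise
  best <- which(youden >= max(youden) - 1e-12)[1]

  ord <- order(fpr, tpr)
  xs <- c(0, fpr[ord], 1)
  ys <- c(0, tpr[ord], 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)

  structure(list(
    cutoff = thresholds[best], auc = auc,
    roc = tibble::tibble(threshold = thresholds, tpr = tpr, fpr = fpr,
                         youden = youden),
    n_used = length(hl$score), n_excluded = hl$n_excluded,
    horizon_days = horizon_days
  ), class = "cutoff_result")
}

#' Compare survival between sample groups
#'
#' Standard log-rank test plus per-group Kaplan-Meier estimates.
#'
#' @param groups Tibble with `sample` and `group`, or a named character
#'   vector of group labels.
#' @param clinical Clinical tibble.
#' @return An object of class `survival_comparison`: list with `chisq`, `df`,
#'   `p`, `km` (tibble `group`, `time`, `surv`, `n_risk`, `n_event`) and
#'   `n_per_group`.
#' @export
compare_groups <- function(groups, clinical) {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(sample = names(groups), group = unname(groups))
  }
  validate_clinical(clinical)
  merged <- dplyr::inner_join(groups, clinical, by = "sample")
  counts <- table(merged$group)
  if (length(counts) < 2) stop("need at least 2 non-empty groups")
  if (any(counts == 0)) stop("group with zero samples: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group,
                           data = merged)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)

  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ group,
                          data = merged)
  strata_labels <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  km <- tibble::tibble(group = strata_labels, time = sf$time, surv = sf$surv,
                       n_risk = sf$n.risk, n_event = sf$n.event)
  km <- dplyr::bind_rows(
    tibble::tibble(group = names(counts), time = 0, surv = 1,
                   n_risk = as.integer(counts), n_event = 0L),
    km) |> dplyr::arrange(.data$group, .data$time)

  structure(list(chisq = unname(sd$chisq), df = df, p = p, km = km,
                 n_per_group = tibble::tibble(group = names(counts),
                                              n = as.integer(counts))),
            class = "survival_comparison")
}

#' Test whether the risk score is an independent prognostic factor
#'
#' Fits a univariate Cox model per clinical covariate and for the risk
#' score, then one joint multivariate model. Rows with missing covariate
#' values are dropped listwise with a message; a covariate with 20% or more
#' missingness, or a numeric covariate pair correlated above 0.999, is an
#' error.
#'
#' @param scores Tibble with `sample` and `risk_score`.
#' @param clinical Clinical tibble holding the covariates.
#' @param covariates Character vector of covariate column names; defaults to
#'   whichever of `age`, `stage`, `t_stage`, `grade`, `gender` are present.
#' @return An object of class `independence_result`: list of tibbles
#'   `univariate` and `multivariate` (columns `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`).
#' @export
independence_analysis <- function(scores, clinical, covariates = NULL) {
  validate_clinical(clinical)
  if (is.null(covariates)) {
    covariates <- intersect(c("age", "stage", "t_stage", "grade", "gender"),
                            colnames(clinical))
  }
  missing_cols <- setdiff(covariates, colnames(clinical))
  if (length(missing_cols) > 0) {
    stop("covariate(s) absent from clinical table: ",
         paste(missing_cols, collapse = ", "))
  }
  merged <- dplyr::inner_join(scores, clinical, by = "sample")
  for (v in covariates) {
    if (mean(is.na(merged[[v]])) >= 0.2) {
      stop("covariate '", v, "' has >= 20% missing values")
    }
  }
  complete <- stats::complete.cases(merged[c("os_time", "os_event",
                                             "risk_score", covariates)])
  if (any(!complete)) {
    message(sprintf("dropping %d sample(s) with missing covariate values", sum(!complete)))
    merged <- merged[complete, ]
  }
  num_vars <- c("risk_score", covariates[vapply(merged[covariates], is.numeric, TRUE)])
  if (length(num_vars) > 1) {
    cm <- stats::cor(merged[num_vars])
    diag(cm) <- 0
    if (any(abs(cm) > 0.999)) {
      idx <- which(abs(cm) > 0.999, arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", num_vars[idx[1]], " and ", num_vars[idx[2]])
    }
  }
  y <- survival::Surv(merged$os_time, merged$os_event)
  uni <- purrr::map_dfr(c(covariates, "risk_score"), function(v) {
    fit <- survival::coxph(stats::as.formula(paste("y ~", v)), data = merged)
    cox_tidy(fit)
  })
  multi_fit <- survival::coxph(
    stats::as.formula(paste("y ~", paste(c(covariates, "risk_score"),
                                         collapse = " + "))),
    data = merged)
  structure(list(univariate = uni, multivariate = cox_tidy(multi_fit)),
            class = "independence_result")
}

#' Harrell's concordance index of a risk score
#'
#' Fraction of usable pairs whose predicted risk ordering agrees with the
#' observed survival ordering (ties count one half). Computed with
#' [survival::concordance()]; higher scores are taken to mean higher risk.
#'
#' @param scores Tibble with `sample` and `risk_score`.
#' @param clinical Clinical tibble.
#' @return The concordance index in \[0, 1\].
#' @export
concordance_index <- function(scores, clinical) {
  validate_clinical(clinical)
  merged <- dplyr::inner_join(scores, clinical, by = "sample")
  cc <- survival::concordance(
    survival::Surv(os_time, os_event) ~ risk_score, data = merged,
    reverse = TRUE)
  unname(cc$concordance)
}
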