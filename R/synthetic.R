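#' Specify a synthetic tumor cohort
#'
#' Defines the generating model for a synthetic cohort carrying the
#' statistical structure the downstream analyses assume: per-gene log-normal
#' expression; planted prognostic gene pairs whose within-sample order
#' indicator enters a proportional-hazards linear predictor; a per-sample
#' nonsynonymous mutation count linked to survival through `tmb_beta`;
#' group-specific expression shifts (differential-expression structure); and
#' CpG probes whose beta values are copula-linked to a target gene's
#' expression with chosen sign and strength.
#'
#' @param n_samples Number of tumor samples (default 400, the scale of a
#'   single-site TCGA cohort).
#' @param n_genes Number of genes in the expression matrix.
#' @param n_immune_genes Number of genes flagged as immune-related; these are
#'   the first `n_immune_genes` gene symbols and are the pairing universe.
#' @param driver_pairs Tibble with columns `gene_a`, `gene_b`, `beta` giving
#'   the planted pair effects (log-hazard per unit indicator). `NULL` plants
#'   `n_driver_pairs` disjoint immune-gene pairs with `|beta| = driver_beta`
#'   and alternating sign.
#' @param n_driver_pairs,driver_beta Used only when `driver_pairs` is `NULL`.
#' @param tmb_beta Log-hazard per mutation-per-megabase unit of TMB. Negative
#'   values give high-TMB samples the better prognosis.
#' @param baseline_hazard Baseline event rate per day (default 6e-4, median
#'   survival about 3.2 years at the reference level).
#' @param censor_rate Censoring rate per day; 0 disables censoring.
#' @param weibull_shape Shape of the event-time distribution; 1 (default)
#'   gives exponential times with closed-form checks.
#' @param deg_shifts Tibble with columns `gene`, `group`, `shift` adding
#'   `shift` standard deviations to `gene`'s expression in the samples of
#'   `group` (`"tmb_high"`/`"tmb_low"` for the median-TMB strata,
#'   `"risk_high"`/`"risk_low"` for the median strata of the generating
#'   linear predictor). `NULL` plants 30 genes shifted by 1.2 SD in the
#'   high-TMB stratum, half of them also shifted in the high-risk stratum,
#'   partly inside the immune list.
#' @param meth_links Tibble with columns `probe`, `gene`, `rho` planting
#'   probe-expression correlations. `NULL` plants two negative (-0.4) and one
#'   positive (+0.4) link to `meth_target`, mirroring the promoter
#'   hyper-/hypomethylation pattern the pipeline is designed to detect.
#' @param meth_target Target gene for the default methylation links.
#' @param n_probes Total number of CpG probes (links plus independent noise).
#' @param n_normal Number of normal (non-tumor) methylation samples.
#' @param normal_offset Beta-scale offset applied to linked probes in normal
#'   samples (default -0.04: tumors slightly hypermethylated).
#' @param mut_mean,mut_size Negative-binomial mean and size for per-sample
#'   total mutation counts (default mean 150 over a 38 Mb exome, i.e. median
#'   TMB near 4/Mb).
#' @param class_probs Named probabilities over variant classifications used
#'   when drawing mutation records; see [default_class_probs()].
#' @param exome_mb Exome size used to convert counts to TMB inside the
#'   generating linear predictor.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 400, n_genes = 1000, n_immune_genes = 50,
                        driver_pairs = NULL, n_driver_pairs = 10,
                        driver_beta = 0.8, tmb_beta = -0.12,
                        baseline_hazard = 6e-4, censor_rate = 4e-4,
                        weibull_shape = 1, deg_shifts = NULL,
                        meth_links = NULL, meth_target = NULL, n_probes = 50,
                        n_normal = 20, normal_offset = -0.04, mut_mean = 150,
                        mut_size = 2, class_probs = default_class_probs(),
                        exome_mb = 38, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 2, n_immune_genes >= 2,
            n_immune_genes <= n_genes, baseline_hazard > 0, censor_rate >= 0,
            weibull_shape > 0, mut_mean > 0, mut_size > 0, exome_mb > 0,
            n_normal >= 0)
  genes <- sprintf("G%04d", seq_len(n_genes))
  immune_genes <- genes[seq_len(n_immune_genes)]

  if (is.null(driver_pairs)) {
    stopifnot(2 * n_driver_pairs <= n_immune_genes)
    idx <- seq_len(2 * n_driver_pairs)
    driver_pairs <- tibble::tibble(
      gene_a = genes[idx[c(TRUE, FALSE)]],
      gene_b = genes[idx[c(FALSE, TRUE)]],
      beta = driver_beta * rep_len(c(1, -1), n_driver_pairs)
    )
  }
  driver_pairs <- tibble::as_tibble(driver_pairs)
  absent <- setdiff(c(driver_pairs$gene_a, driver_pairs$gene_b), genes)
  if (length(absent) > 0) {
    stop("driver pair names gene(s) absent from the cohort: ",
         paste(absent, collapse = ", "))
  }

  if (is.null(deg_shifts)) {
    # 30 genes shifted in the high-TMB stratum, straddling the immune-list
    # boundary and clear of the drivers; half are also shifted in the
    # high-risk stratum so the two DEG sets share a planted core
    start <- min(2 * n_driver_pairs + 11L, n_genes)
    tmb_idx <- seq(start, min(start + 29L, n_genes))
    risk_idx <- seq(start + 15L, min(start + 44L, n_genes))
    deg_shifts <- dplyr::bind_rows(
      tibble::tibble(gene = genes[tmb_idx], group = "tmb_high", shift = 1.2),
      tibble::tibble(gene = genes[risk_idx], group = "risk_high", shift = 1.2))
  }
  deg_shifts <- tibble::as_tibble(deg_shifts)
  shift_groups <- c("tmb_high", "tmb_low", "risk_high", "risk_low")
  if (nrow(deg_shifts) > 0 && !all(deg_shifts$group %in% shift_groups)) {
    stop("deg_shifts groups must be one of: ", paste(shift_groups, collapse = ", "))
  }

  if (is.null(meth_target)) meth_target <- genes[1]
  if (is.null(meth_links)) {
    meth_links <- tibble::tibble(
      probe = c("cg00000001", "cg00000002", "cg00000003"),
      gene = meth_target,
      rho = c(-0.4, -0.4, 0.4)
    )
  }
  meth_links <- tibble::as_tibble(meth_links)
  if (any(abs(meth_links$rho) > 1)) stop("|rho| must be <= 1 in meth_links")
  if (nrow(meth_links) > n_probes) stop("n_probes smaller than number of methylation links")

  structure(list(
    n_samples = n_samples, n_genes = n_genes, genes = genes,
    immune_genes = immune_genes, driver_pairs = driver_pairs,
    tmb_beta = tmb_beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, weibull_shape = weibull_shape,
    deg_shifts = deg_shifts, meth_links = meth_links, n_probes = n_probes,
    n_normal = n_normal, normal_offset = normal_offset, mut_mean = mut_mean,
    mut_size = mut_size, class_probs = class_probs, exome_mb = exome_mb,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default variant-classification distribution for simulated mutations
#'
#' Missense-dominant mix over the nine nonsynonymous classes plus a Silent
#' fraction, so that nonsynonymous-only TMB filtering is exercised.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_class_probs <- function() {
  p <- c(Missense_Mutation = 0.58, Nonsense_Mutation = 0.06,
         Splice_Site = 0.05, Frame_Shift_Del = 0.05, Frame_Shift_Ins = 0.03,
         In_Frame_Del = 0.02, In_Frame_Ins = 0.01,
         Translation_Start_Site = 0.005, Nonstop_Mutation = 0.005,
         Silent = 0.19)
  p / sum(p)
}

#' Generate a complete synthetic cohort
#'
#' Draws expression, mutations, survival and methylation under the
#' proportional-hazards generating model of the [cohort_spec()]. Per-gene
#' expression is log-normal (normal on the log2 scale); gene means within a
#' planted driver pair are kept close so the pair's order indicator is
#' balanced across samples. The linear predictor is the sum of the planted
#' pair effects (indicators centered at 1/2) and `tmb_beta` times the
#' mean-centered per-sample TMB. Group expression shifts are applied after
#' survival is drawn, so they create differential-expression structure
#' without perturbing the planted survival signal.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (gene x sample matrix), `clinical` (tibble), `maf` (mutation tibble),
#'   `methylation` (`meth_set`), `meth_groups` (tibble `sample`, `group`),
#'   `immune_genes`, `tmb_truth` (tibble of generating TMB values),
#'   `linear_predictor` (the generating log-hazard, for diagnostics) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  genes <- spec$genes
  samples <- sprintf("S%04d", seq_len(spec$n_samples))

  mu <- stats::runif(spec$n_genes, 2, 10)
  sd <- stats::runif(spec$n_genes, 0.5, 1.5)
  names(mu) <- names(sd) <- genes
  # keep driver-pair gene means close so the pair indicator is balanced
  for (k in seq_len(nrow(spec$driver_pairs))) {
    a <- spec$driver_pairs$gene_a[k]; b <- spec$driver_pairs$gene_b[k]
    mu[b] <- mu[a] + stats::rnorm(1, 0, 0.2)
  }
  expr <- matrix(stats::rnorm(spec$n_genes * spec$n_samples, mu, sd),
                 nrow = spec$n_genes, ncol = spec$n_samples,
                 dimnames = list(genes, samples))

  lp <- rep(0, spec$n_samples)
  for (k in seq_len(nrow(spec$driver_pairs))) {
    s <- as.numeric(expr[spec$driver_pairs$gene_a[k], ] >
                      expr[spec$driver_pairs$gene_b[k], ])
    lp <- lp + spec$driver_pairs$beta[k] * (s - 0.5)
  }

  maf <- simulate_maf(samples, mut_mean = spec$mut_mean,
                      mut_size = spec$mut_size,
                      class_probs = spec$class_probs)
  nonsyn <- table(factor(maf$sample[maf$variant_classification %in%
                                      nonsynonymous_classes()],
                         levels = samples))
  tmb <- as.numeric(nonsyn) / spec$exome_mb
  names(tmb) <- samples
  lp <- lp + spec$tmb_beta * (tmb - mean(tmb))

  clinical <- simulate_survival(stats::setNames(lp, samples),
                                baseline_hazard = spec$baseline_hazard,
                                censor_rate = spec$censor_rate,
                                shape = spec$weibull_shape)
  clinical$age <- round(stats::rnorm(spec$n_samples, 68, 9))
  clinical$stage <- sample(c("I", "II", "III", "IV"), spec$n_samples,
                           replace = TRUE, prob = c(0.1, 0.3, 0.35, 0.25))

  if (nrow(spec$deg_shifts) > 0) {
    membership <- cbind(
      tmb_high = tmb > stats::median(tmb),
      tmb_low = tmb <= stats::median(tmb),
      risk_high = lp > stats::median(lp),
      risk_low = lp <= stats::median(lp))
    for (k in seq_len(nrow(spec$deg_shifts))) {
      g <- spec$deg_shifts$gene[k]
      in_group <- membership[, spec$deg_shifts$group[k]]
      expr[g, in_group] <- expr[g, in_group] + spec$deg_shifts$shift[k] * sd[g]
    }
  }

  meth <- simulate_methylation(spec$meth_links, expr, n_probes = spec$n_probes,
                               n_normal = spec$n_normal,
                               normal_offset = spec$normal_offset)

  structure(list(
    expression = expr, clinical = clinical, maf = maf,
    methylation = meth$meth, meth_groups = meth$groups,
    immune_genes = spec$immune_genes,
    tmb_truth = tibble::tibble(sample = samples, tmb = tmb),
    linear_predictor = stats::setNames(lp, samples), spec = spec
  ), class = "synthetic_cohort")
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times follow a Weibull proportional-hazards model with baseline rate
#' `baseline_hazard` and shape `shape` (shape 1 gives exponential times with
#' rate `baseline_hazard * exp(lp)`); censoring times are exponential with
#' rate `censor_rate`. The observed time is the minimum and the event flag
#' records whether the event preceded censoring.
#'
#' @param linear_predictor Named numeric vector: per-sample log hazard ratio.
#' @param baseline_hazard Baseline event rate per day; must be > 0.
#' @param censor_rate Censoring rate per day; 0 disables censoring.
#' @param shape Weibull shape parameter (1 = exponential).
#' @param seed Optional integer seed.
#' @return Tibble with columns `sample`, `os_time` (days), `os_event`.
#' @export
simulate_survival <- function(linear_predictor, baseline_hazard, censor_rate,
                              shape = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(is.finite(linear_predictor))) stop("linear predictor must be finite")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_rate < 0) stop("censor_rate must be non-negative")
  if (shape <= 0) stop("weibull shape must be positive")
  n <- length(linear_predictor)
  ids <- names(linear_predictor)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  # inverse-transform Weibull PH: S(t) = exp(-h0 * exp(lp) * t^shape)
  u <- stats::runif(n)
  t_event <- (-log(u) / (baseline_hazard * exp(linear_predictor)))^(1 / shape)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  tibble::tibble(
    sample = ids,
    os_time = unname(pmin(t_event, t_cens)),
    os_event = unname(as.numeric(t_event <= t_cens))
  )
}

#' Simulate a per-sample somatic mutation table
#'
#' Per-sample total mutation counts are negative binomial; each record draws
#' a gene from a rank-weighted universe (so a handful of recurrently mutated
#' genes emerges), a variant classification from `class_probs`, and alleles
#' consistent with the classification. For SNPs the substitution is drawn
#' with a transition-heavy distribution (C>T and its reverse-strand
#' equivalent G>A dominate), matching the mutation spectrum typical of
#' somatic exomes.
#'
#' @param samples Character vector of sample ids.
#' @param mut_mean,mut_size Negative-binomial mean and size of total counts.
#' @param class_probs Named probability vector over variant classifications.
#' @param n_mut_genes Size of the mutable gene universe.
#' @param seed Optional integer seed.
#' @return A tibble of class `maf_tbl` (same columns as [read_maf()]).
#' @export
simulate_maf <- function(samples, mut_mean = 150, mut_size = 2,
                         class_probs = default_class_probs(),
                         n_mut_genes = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mut_mean > 0, mut_size > 0, length(samples) >= 1)
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  counts <- stats::rnbinom(length(samples), mu = mut_mean, size = mut_size)
  n_total <- sum(counts)
  mut_genes <- sprintf("MUT%03d", seq_len(n_mut_genes))
  gene_w <- 1 / seq_len(n_mut_genes)^0.8
  classes <- names(class_probs)
  cls <- sample(classes, n_total, replace = TRUE, prob = class_probs)
  vtype <- variant_type_for_class(cls)
  snp <- vtype == "SNP"

  ref <- character(n_total); alt <- character(n_total)
  if (any(snp)) {
    pyr <- sample(snv_classes(), sum(snp), replace = TRUE,
                  prob = c(0.10, 0.08, 0.42, 0.08, 0.22, 0.10))
    flip <- stats::runif(sum(snp)) < 0.5
    sub <- ifelse(flip, complement_substitution(pyr), pyr)
    ref[snp] <- substr(sub, 1, 1)
    alt[snp] <- substr(sub, 3, 3)
  }
  is_del <- vtype == "DEL"; is_ins <- vtype == "INS"
  ref[is_del] <- sample(c("A", "C", "G", "T"), sum(is_del), replace = TRUE)
  alt[is_del] <- "-"
  ref[is_ins] <- "-"
  alt[is_ins] <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)

  maf <- tibble::tibble(
    sample = rep(samples, counts),
    gene = sample(mut_genes, n_total, replace = TRUE, prob = gene_w),
    variant_classification = cls,
    variant_type = vtype,
    chromosome = as.character(sample(1:22, n_total, replace = TRUE)),
    position = sample.int(2e8, n_total, replace = TRUE),
    ref_allele = ref,
    alt_allele = alt
  )
  class(maf) <- c("maf_tbl", class(maf))
  maf
}

variant_type_for_class <- function(cls) {
  dplyr::case_when(
    cls %in% c("Frame_Shift_Del", "In_Frame_Del") ~ "DEL",
    cls %in% c("Frame_Shift_Ins", "In_Frame_Ins") ~ "INS",
    TRUE ~ "SNP"
  )
}

#' Simulate CpG beta values linked to gene expression
#'
#' For each planted link the probe's latent value is a Gaussian copula draw
#' correlated at `rho` with the target gene's (standardized) expression,
#' squashed to \[0, 1\] through the logistic function; the realized Pearson
#' correlation is mildly attenuated by the squash but stays well within the
#' Monte-Carlo tolerance used in tests. Unlinked probes are independent Beta
#' noise. Normal samples are generated independently of tumor expression and
#' shifted by `normal_offset` on linked probes.
#'
#' @param meth_links Tibble with columns `probe`, `gene`, `rho`.
#' @param expression Gene x sample expression matrix (tumor samples).
#' @param n_probes Total probe count (links plus noise probes).
#' @param n_normal Number of normal samples appended to the matrix.
#' @param normal_offset Beta-scale offset for linked probes in normals.
#' @param seed Optional integer seed.
#' @return List with `meth` (a [meth_set()]) and `groups` (tibble `sample`,
#'   `group` in {tumor, normal}).
#' @export
simulate_methylation <- function(meth_links, expression, n_probes = 50,
                                 n_normal = 20, normal_offset = -0.04,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meth_links <- tibble::as_tibble(meth_links)
  if (any(abs(meth_links$rho) > 1)) stop("|rho| must be <= 1")
  absent <- setdiff(meth_links$gene, rownames(expression))
  if (length(absent) > 0) {
    stop("meth_links name gene(s) absent from expression: ",
         paste(absent, collapse = ", "))
  }
  tumor <- colnames(expression)
  normals <- if (n_normal > 0) sprintf("N%03d", seq_len(n_normal)) else character()
  n_noise <- n_probes - nrow(meth_links)

  beta <- matrix(NA_real_, nrow = n_probes, ncol = length(tumor) + n_normal)
  probe_ids <- c(meth_links$probe,
                 if (n_noise > 0) sprintf("cg1%07d", seq_len(n_noise)))
  dimnames(beta) <- list(probe_ids, c(tumor, normals))

  for (k in seq_len(nrow(meth_links))) {
    rho <- meth_links$rho[k]
    z_expr <- as.numeric(scale(expression[meth_links$gene[k], ]))
    mu_p <- stats::runif(1, -0.6, 0.6)
    z <- rho * z_expr + sqrt(1 - rho^2) * stats::rnorm(length(tumor))
    beta[k, tumor] <- stats::plogis(mu_p + 0.5 * z)
    if (n_normal > 0) {
      zn <- stats::rnorm(n_normal)
      bn <- stats::plogis(mu_p + 0.5 * zn) + normal_offset
      beta[k, normals] <- pmin(pmax(bn, 0), 1)
    }
  }
  if (n_noise > 0) {
    for (k in seq_len(n_noise)) {
      m <- stats::runif(1, 0.2, 0.8)
      beta[nrow(meth_links) + k, ] <- stats::rbeta(ncol(beta), m * 20, (1 - m) * 20)
    }
  }

  other_genes <- setdiff(rownames(expression), meth_links$gene)
  map <- tibble::tibble(
    probe = probe_ids,
    gene = c(meth_links$gene,
             if (n_noise > 0) sample(other_genes, n_noise, replace = TRUE))
  )
  list(
    meth = meth_set(beta, map),
    groups = tibble::tibble(
      sample = c(tumor, normals),
      group = rep(c("tumor", "normal"), c(length(tumor), n_normal))
    )
  )
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `expression.tsv`, `clinical.tsv`, `mutations.maf`,
#' `methylation.tsv`, `probe_map.tsv`, `meth_groups.tsv`,
#' `immune_genes.txt` and `spec.yaml`, the directory layout [run_pipeline()]
#' consumes.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_maf(cohort$maf, file.path(dir, "mutations.maf"))
  write_methylation(cohort$methylation, file.path(dir, "methylation.tsv"),
                    file.path(dir, "probe_map.tsv"))
  readr::write_tsv(cohort$meth_groups, file.path(dir, "meth_groups.tsv"),
                   progress = FALSE)
  writeLines(cohort$immune_genes, file.path(dir, "immune_genes.txt"))
  spec_plain <- cohort$spec
  spec_plain$driver_pairs <- as.data.frame(spec_plain$driver_pairs)
  spec_plain$deg_shifts <- as.data.frame(spec_plain$deg_shifts)
  spec_plain$meth_links <- as.data.frame(spec_plain$meth_links)
  yaml::write_yaml(lapply(unclass(spec_plain), function(x)
    if (is.data.frame(x)) as.list(x) else x), file.path(dir, "spec.yaml"))
  invisible(dir)
}
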