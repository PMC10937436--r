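# small in-code fixtures shared across test files

tiny_maf <- function(sample, gene, classification, type = NULL,
                     ref = "C", alt = "T") {
  n <- length(sample)
  if (is.null(type)) type <- rep("SNP", n)
  maf <- tibble::tibble(
    sample = sample, gene = gene,
    variant_classification = classification, variant_type = type,
    chromosome = rep("1", n), position = seq_len(n),
    ref_allele = rep_len(ref, n), alt_allele = rep_len(alt, n))
  class(maf) <- c("maf_tbl", class(maf))
  maf
}

tiny_expr <- function(n_genes = 6, n_samples = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples,
         dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

tiny_clinical <- function(n = 8, seed = 1) {
  set.seed(seed)
  tibble::tibble(sample = sprintf("S%02d", seq_len(n)),
                 os_time = round(runif(n, 50, 2500)),
                 os_event = rbinom(n, 1, 0.6))
}

# random MAF over a few samples/genes for oracle comparisons
random_maf <- function(n_records = 30, n_samples = 5, seed = 1) {
  set.seed(seed)
  classes <- c(nonsynonymous_classes(), "Silent", "3'UTR", "Intron")
  tiny_maf(
    sample = sprintf("S%d", sample.int(n_samples, n_records, replace = TRUE)),
    gene = sprintf("G%d", sample.int(12, n_records, replace = TRUE)),
    classification = sample(classes, n_records, replace = TRUE),
    type = sample(c("SNP", "DEL", "INS"), n_records, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1)))
}

# hand-computed two-group log-rank statistic (observed minus expected over
# distinct event times, hypergeometric variance)
logrank_chisq_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# exhaustive midpoint search maximizing the Youden index (count-based,
# strict-improvement rule so ties resolve to the lowest cutoff)
youden_oracle <- function(score, label) {
  s <- sort(unique(score))
  mids <- (s[-1] + s[-length(s)]) / 2
  best_j <- -Inf
  best <- NA_real_
  for (cth in mids) {
    tp <- sum(score > cth & label == 1)
    fn <- sum(score <= cth & label == 1)
    fp <- sum(score > cth & label == 0)
    tn <- sum(score <= cth & label == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-9) {
      best_j <- j
      best <- cth
    }
  }
  list(cutoff = best, j = best_j)
}

# clinical table realizing given horizon labels (1 = death before horizon)
clinical_from_labels <- function(sample, label, horizon = 1825) {
  tibble::tibble(sample = sample,
                 os_time = ifelse(label == 1, horizon / 2, horizon + 100),
                 os_event = as.numeric(label == 1))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
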