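---
title: "Methods: rank-based gene-pair prognostic modelling with TMB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene-pair prognostic modelling with TMB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`irgprog` implements a prognostic analysis for tumor cohorts that combines
two complementary views of the tumor-immune interface: per-sample tumor
mutational burden (TMB) computed from somatic mutation tables, and a
rank-based risk model built from immune-related gene pairs (IRGPs). This
vignette records the model, its assumptions, the tunable parameters and the
design decisions, so that results can be interpreted and the package
extended without reverse-engineering the code.

## The pair indicator and why it is rank-based

For an unordered pair of immune genes (a, b), canonically ordered with a
lexicographically before b, the indicator for sample *i* is 1 exactly when
gene a's expression strictly exceeds gene b's in that sample; ties score 0.
Two consequences drive the design:

* **Monotone invariance.** Any strictly increasing transform of the
  expression values — a change of normalization, a log, a platform-specific
  rescaling — leaves every indicator unchanged. A fitted pair model can
  therefore score a validation cohort measured on a different platform
  without renormalization. This is the package's central correctness
  property and is tested with randomized transform families.
* **Information lives in balanced pairs.** A pair whose ordering is the
  same in (almost) every sample cannot discriminate outcomes.
  `filter_pairs()` retains pairs whose indicator frequency lies in
  `[min_freq, 1 - min_freq]`, default `[0.2, 0.8]`.

The balance filter deserves a note. For a binary indicator the median
absolute deviation is identically zero, so a MAD threshold cannot be applied
to indicators literally; a frequency band is the direct way to demand
variability of a binary feature. The band is configurable, and an expression-level
MAD filter before pairing can be emulated by pre-filtering the matrix
passed to `build_pair_matrix()`. Practitioners targeting a sparser candidate
set (the published pair signatures keep roughly 1–2% of all candidate
pairs) should tighten the band.

## Survival model and selection path

The risk model is a linear Cox proportional-hazards predictor over pair
indicators, built in three stages:

1. **Univariate screen** (`univariate_screen()`): one Cox fit per pair,
   retaining pairs with score-test p below `screen_p`. The score test is
   used because it stays informative when a binary feature perfectly
   separates risk sets. The default threshold is 0.01. This is
   deliberately less stringent than fixed genome-wide-style cutoffs: when
   many prognostic features act simultaneously, the *marginal* hazard ratio
   of each is attenuated (Cox models are non-collapsible — omitted
   covariates act as frailty), and an over-tight screen silently discards
   true effects. Recovery experiments on synthetic cohorts with ten planted
   pairs of log-hazard 0.8 showed marginal log-hazards shrunk to roughly
   0.5–0.6; at a candidate universe of ~1200 pairs, `screen_p = 0.01`
   passes a few dozen candidates to the penalized fit while retaining
   effects of that size.
2. **Penalized fit** (`fit_model()`): lasso Cox over the screened
   candidates, penalty chosen by 10-fold cross-validated partial-likelihood
   deviance at its minimum. Fold assignment derives from an explicit seed,
   so the selected set is reproducible. Exactly duplicated feature rows are
   collapsed (first kept) before fitting so the L1 solution is unique over
   the retained set. Backward stepwise selection is available as a
   classical alternative.
3. **Scoring and cutoff** (`score_samples()`, `optimal_cutoff()`): the risk
   score is the coefficient-weighted indicator sum. The high/low cutoff
   maximizes the Youden index on the ROC for death by a fixed horizon
   (default 1825 days = 5 years; days are the package-wide time unit).
   Patients censored before the horizon are excluded from ROC labelling —
   the simple estimator; an inverse-probability-of-censoring weighted
   variant was considered and left out of scope because the downstream
   decisions (a cutoff) are insensitive to the refinement at the cohort
   sizes targeted. Candidate cutoffs are midpoints between consecutive
   distinct scores; ties in the Youden index resolve to the lowest cutoff,
   with a 1e-12 numerical tolerance so floating-point noise cannot flip the
   tie rule. Samples score "high risk" strictly above the cutoff.

Group survival contrasts use the standard log-rank test and Kaplan-Meier
estimates (`compare_groups()`), and `independence_analysis()` fits
univariate and joint multivariate Cox models of the risk score against
clinical covariates, dropping rows with missing covariates listwise and
refusing covariate pairs correlated above 0.999.

## TMB

`compute_tmb()` divides the per-sample count of nonsynonymous mutations by
the exome size in megabases. The counted classes default to the nine
protein-altering classes (missense, nonsense, nonstop, splice site,
frame-shift and in-frame indels, translation start site); Silent and
flank/UTR classes are excluded, following the convention that TMB counts
nonsynonymous events. Both the class filter and the denominator
(`exome_mb`, default 38 Mb, a common exome-capture size) are configuration
knobs because upstream pipelines differ. The median split sends ties to the
low group — a deterministic reading of "high = above the median" — and an
all-equal TMB vector is a hard error rather than an arbitrary split.

Dichotomization costs power: with a skewed (negative-binomial) TMB
distribution, a continuous Cox fit recovers a planted TMB effect far more
efficiently than the median-split log-rank, because much of the signal sits
in the long upper tail that the split collapses. The package reports the
split-based contrast for comparability with common practice, but the
continuous fit is available through `univariate_screen()` on the TMB vector.

Pairwise co-occurrence and mutual exclusivity of the top mutated genes use
the two-sided Fisher exact test per gene pair with Benjamini-Hochberg
adjustment across pairs (`mutation_interactions()`); both raw and adjusted
p-values are reported because practice marks significance at more than one
tier.

## Differential expression and candidate genes

`differential_expression()` applies a per-gene two-sided Wilcoxon rank-sum
test (normal approximation with tie and continuity corrections — verified
against `stats::wilcox.test` to 1e-12 in the tests) with BH adjustment
across genes. The DEG rule is FDR < 0.05 with no fold-change cutoff by
default, since the variance-stabilized rank test already guards against
tiny-shift artifacts; `logfc_threshold` is available. The log fold change
is a difference of group means on the log2 scale, so its magnitude does
depend on the upstream normalization even though the pair model does not.

DEG sets from the TMB grouping and the risk grouping are intersected
(`intersect_deg_sets()`); the common genes get univariate and joint
multivariate Cox fits plus median-split KM tests (`gene_cox_table()`, with
hazard ratios per unit of continuous log2 expression), are ranked by
absolute standardized lasso Cox coefficient (`prioritize_genes()` — the
top-ranked gene is the operational "key gene"), and pairwise Spearman
correlations are reported (`gene_correlations()`). `ddct_fold_change()`
implements the 2^-ddCt relative quantification used when validating a
candidate by qPCR: replicate Ct values are averaged per sample before the
delta steps, and a shared Ct offset cancels exactly.

## Methylation

Gene-level methylation is the unweighted mean beta over all probes mapped
to the gene (no promoter restriction is imposed because probe maps often
lack region annotations; restricting the map restricts the aggregate).
Tumor-normal contrasts use the rank-sum test at gene and probe level, with
BH adjustment across probes and hyper/hypo status by the sign of the
tumor-minus-normal mean difference. Probe-expression correlation defaults
to Pearson — beta values in the mid-range are approximately linear in the
underlying signal — with Spearman as an option for saturated probes.

## The synthetic cohort generator

`generate_cohort()` draws, under one seed that fully determines the output:

* per-gene log-normal expression (normal on the log2 scale, means uniform
  on [2, 10], SDs on [0.5, 1.5]); driver-pair gene means are kept within a
  0.2-SD draw of each other so planted pair indicators are balanced;
* planted pair effects entering a proportional-hazards linear predictor
  through centered indicators (defaults: 10 disjoint immune pairs,
  |beta| = 0.8, alternating sign);
* negative-binomial mutation counts (mean 150 over a 38 Mb exome, i.e.
  median TMB near 4/Mb; size 2) drawn as MAF records with a
  missense-dominant, transition-heavy spectrum; the realized nonsynonymous
  TMB feeds the linear predictor with coefficient `tmb_beta` (default
  -0.12 per mutation/Mb, protective, matching the direction reported for
  bladder tumor cohorts);
* exponential event times at baseline hazard 6e-4/day (median survival
  about 3.2 years at the reference level) and exponential censoring at
  4e-4/day (roughly 40% censoring); a Weibull shape is exposed;
* group expression shifts of 1.2 SD for 30 genes in the high-TMB stratum,
  half of them also shifted in the high-risk stratum, straddling the
  immune-list boundary — this plants DEG structure and a nonempty DEG
  intersection;
* CpG probes copula-linked to a target gene (Gaussian latent variable
  correlated at rho, logistic-squashed to [0, 1]; the squash attenuates
  the realized Pearson correlation by a few percent, well inside the
  +/-0.15 recovery tolerance used in tests), defaults -0.4, -0.4, +0.4,
  plus independent Beta-noise probes and normal samples offset by -0.04
  on linked probes (tumors slightly hypermethylated).

What the generator does *not* emulate: mutational signatures and gene-level
mutation hotspots beyond a rank-weighted recurrence gradient, copy-number
structure, batch effects, correlated co-expression modules, or realistic
censoring mechanisms (administrative rather than exponential). Passing
tests therefore demonstrate that the estimators recover the structure they
model under clean conditions — not that any specific biological cohort
satisfies those conditions.

## Problem sizes and stochastic checks

The test suite validates the arithmetic against independent oracles
(brute-force TMB counting, hypergeometric enumeration for the Fisher test
on all 2x2 tables up to n = 20, a hand-written observed-minus-expected
log-rank computation, exhaustive midpoint search for the Youden cutoff) and
runs recovery experiments at the scale the estimators target: 400 training
plus 200 validation samples with 1225 candidate pairs for the end-to-end
chain, n = 1000 for the TMB split, 2000 genes at 100 samples per group for
FDR control, n = 300 for methylation links. Stochastic assertions are run
at fixed seeds with bounds chosen from the generating model (binomial
envelopes for calibration checks, Monte-Carlo tolerances for recovery);
the held-out concordance bound in particular sits close to the generating
model's own ceiling at these sample sizes, so it certifies near-optimal
estimation rather than a comfortable margin.

## Known limitations

* The Wilcoxon engine always uses the normal approximation; exact p-values
  for very small groups (< ~10 per arm) are not computed.
* The univariate/multivariate Cox fits report Wald intervals; profile
  likelihood intervals are not implemented.
* `run_pipeline()` selects the methylation target gene as the top-ranked
  candidate with mapped probes; when the DEG intersection is empty the
  methylation stage falls back to the most-probed gene, which may not be
  biologically interesting.
* Sample-id intersection across inputs is silent beyond a message; no
  barcode normalization (e.g. TCGA aliquot suffixes) is attempted.
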