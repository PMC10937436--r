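Package: irgprog
Title: Immune-Related Gene-Pair Prognostic Modelling with Tumor Mutational Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rank-based immune-related gene-pair (IRGP) prognostic
    signatures for tumor cohorts and integrates them with tumor mutational
    burden (TMB) analysis. Provides readers for MAF-style somatic mutation
    tables, expression matrices, clinical tables and CpG methylation matrices;
    per-sample TMB computation with median-split grouping and pairwise
    mutation co-occurrence testing; construction and balance-filtering of
    binary gene-pair indicator matrices; penalized Cox selection of
    prognostic pairs with risk scoring, survival-ROC cutoff selection,
    Kaplan-Meier comparison and clinical-covariate independence testing;
    rank-sum differential expression with FDR control and DEG-set
    intersection; candidate-gene Cox tables, lasso prioritization, gene
    correlations and relative qPCR quantification; gene- and site-level
    differential methylation and methylation-expression correlation. A
    synthetic-cohort generator with planted pair effects, a TMB-survival
    link, group expression shifts and copula-linked methylation makes every
    stage testable without restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    survival,
    glmnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
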