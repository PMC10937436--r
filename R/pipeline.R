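#' Run the full TMB + gene-pair prognostic analysis
#'
#' Orchestrates the stages end to end from a cohort directory (the layout
#' written by [write_cohort()]): TMB computation and median-split grouping
#' with a survival comparison; TMB-group differential expression; pair
#' matrix construction, balance filtering, univariate screening, penalized
#' model fitting, risk scoring and cutoff selection; risk-group differential
#' expression; DEG intersection and candidate-gene prognostics; and, when
#' methylation files are present, gene- and site-level methylation analyses
#' for the top-ranked candidate gene. Stages whose optional inputs are
#' absent are marked `SKIPPED`; any stage error halts the run with the stage
#' name and cause, retaining the outputs already written.
#'
#' @param input_dir Directory containing `expression.tsv`, `clinical.tsv`,
#'   `mutations.maf`, `immune_genes.txt` and optionally `methylation.tsv`,
#'   `probe_map.tsv`, `meth_groups.tsv`.
#' @param out_dir Output directory for result TSVs and the JSON manifest.
#' @param config A [run_config()].
#' @return A list of class `results_bundle` with `stages` (tibble `stage`,
#'   `status`, `detail`), `outputs` (named list of in-memory results) and
#'   `out_dir`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- list()
  note <- function(stage, status, detail = "") {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, status = status, detail = detail)
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) {
      note(stage, "FAILED", conditionMessage(e))
      write_manifest(out_dir, config, dplyr::bind_rows(stages))
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note(stage, "PASSED")
    res
  }
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }

  inputs <- run_stage("read_inputs", function() {
    expr <- read_expression(file.path(input_dir, "expression.tsv"))
    clinical <- read_clinical(file.path(input_dir, "clinical.tsv"))
    maf <- read_maf(file.path(input_dir, "mutations.maf"))
    immune <- read_gene_list(file.path(input_dir, "immune_genes.txt"))
    keep <- suppressMessages(common_samples(colnames(expr), clinical$sample))
    list(expr = expr[, keep, drop = FALSE],
         clinical = clinical[match(keep, clinical$sample), ],
         maf = maf, immune = immune)
  })
  expr <- inputs$expr; clinical <- inputs$clinical

  tmb_groups <- run_stage("tmb_grouping", function() {
    tmb <- suppressWarnings(compute_tmb(
      inputs$maf, exome_mb = config$exome_mb,
      nonsyn_only = config$nonsyn_only, samples = clinical$sample))
    grouped <- split_by_median(tmb)
    tsv(grouped, "tmb.tsv")
    vs <- suppressMessages(summarize_variants(inputs$maf))
    tsv(vs$by_classification, "variant_classification.tsv")
    tsv(vs$by_snv_class, "variant_snv_class.tsv")
    tsv(suppressMessages(mutation_interactions(inputs$maf)), "interactions.tsv")
    cmp <- compare_groups(
      dplyr::mutate(grouped, group = paste0("tmb_", .data$group)), clinical)
    tsv(cmp$km, "km_tmb_groups.tsv")
    outputs$tmb_comparison <<- cmp
    grouped
  })

  tmb_degs <- run_stage("tmb_degs", function() {
    grp <- tibble::tibble(sample = tmb_groups$sample,
                          group = factor(tmb_groups$group, c("high", "low")))
    deg <- differential_expression(expr, grp,
                                   fdr_threshold = config$fdr_threshold,
                                   logfc_threshold = config$logfc_threshold)
    tsv(deg, "degs_tmb.tsv")
    deg
  })

  model_parts <- run_stage("pair_model", function() {
    ipm <- suppressMessages(build_pair_matrix(expr, inputs$immune))
    ipm <- suppressMessages(filter_pairs(ipm, min_freq = config$min_pair_freq))
    screen <- suppressWarnings(suppressMessages(
      univariate_screen(ipm, clinical, p_threshold = config$screen_p)))
    tsv(screen, "cox_univariate_pairs.tsv")
    cand <- screen$feature[screen$keep]
    if (length(cand) < 2) stop("fewer than 2 pairs pass the univariate screen")
    sub <- structure(list(s = ipm$s[cand, , drop = FALSE],
                          pairs = ipm$pairs[match(cand, ipm$pairs$pair_id), ]),
                     class = "irgp_matrix")
    model <- suppressMessages(fit_model(sub, clinical,
                                        method = config$model_method,
                                        nfolds = config$cv_folds,
                                        seed = config$seed))
    scores <- suppressMessages(score_samples(model, expr))
    cut <- optimal_cutoff(scores, clinical,
                          horizon_days = config$horizon_days)
    model <- set_model_cutoff(model, cut)
    tsv(scores, "risk_scores.tsv")
    tsv(cut$roc, "roc_points.tsv")
    tsv(tidy(model), "model_pairs.tsv")
    jsonlite::write_json(
      list(pairs = model$pairs, method = model$method,
           lambda = model$lambda, cutoff = model$cutoff,
           training_auc = model$training_auc),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    list(ipm = ipm, model = model, scores = scores, cutoff = cut)
  })

  risk_groups <- run_stage("risk_groups", function() {
    grp <- tibble::tibble(
      sample = model_parts$scores$sample,
      group = factor(ifelse(model_parts$scores$risk_score >
                              model_parts$model$cutoff, "high", "low"),
                     c("high", "low")))
    cmp <- compare_groups(grp, clinical)
    tsv(cmp$km, "km_risk_groups.tsv")
    ind <- suppressMessages(independence_analysis(model_parts$scores, clinical))
    tsv(ind$univariate, "cox_univariate_clinical.tsv")
    tsv(ind$multivariate, "cox_multivariate_clinical.tsv")
    outputs$risk_comparison <<- cmp
    outputs$independence <<- ind
    grp
  })

  risk_degs <- run_stage("risk_degs", function() {
    deg <- differential_expression(expr, risk_groups,
                                   fdr_threshold = config$fdr_threshold,
                                   logfc_threshold = config$logfc_threshold)
    tsv(deg, "degs_risk.tsv")
    deg
  })

  candidates <- run_stage("candidate_genes", function() {
    common <- intersect_deg_sets(list(
      tmb = tmb_degs$gene[tmb_degs$deg],
      risk = risk_degs$gene[risk_degs$deg]))
    tsv(tibble::tibble(gene = common$common), "common_degs.tsv")
    immune_degs <- select_immune_degs(tmb_degs, inputs$immune)
    tsv(tibble::tibble(gene = immune_degs), "immune_degs_tmb.tsv")
    if (length(common$common) == 0) {
      return(list(common = common, prognosis = NULL, ranking = NULL))
    }
    prog <- suppressWarnings(suppressMessages(
      gene_cox_table(expr, clinical, common$common)))
    tsv(prog, "gene_prognosis.tsv")
    ranking <- NULL
    if (length(common$common) >= 2) {
      ranking <- suppressMessages(prioritize_genes(
        expr, clinical, common$common, nfolds = config$cv_folds,
        seed = config$seed))
      tsv(ranking, "gene_ranking.tsv")
      if (length(common$common) >= 2 && ncol(expr) >= 10) {
        gc <- suppressWarnings(gene_correlations(expr, common$common))
        tsv(gc$correlations, "gene_correlations.tsv")
      }
    }
    list(common = common, prognosis = prog, ranking = ranking)
  })

  meth_path <- file.path(input_dir, "methylation.tsv")
  if (file.exists(meth_path)) {
    run_stage("methylation", function() {
      meth <- suppressWarnings(read_methylation(
        meth_path, file.path(input_dir, "probe_map.tsv")))
      grp_path <- file.path(input_dir, "meth_groups.tsv")
      groups <- if (file.exists(grp_path)) {
        readr::read_tsv(grp_path, col_types = "cc", progress = FALSE)
      } else {
        tibble::tibble(sample = colnames(meth$beta), group = "tumor")
      }
      mapped <- unique(meth$probe_map$gene)
      ranked <- candidates$ranking$gene
      target <- c(intersect(ranked, mapped), mapped)[1]
      if (all(c("tumor", "normal") %in% groups$group)) {
        gl <- gene_level_methylation(meth, target, groups)
        tsv(gl$group_means, "gene_methylation.tsv")
        tsv(suppressMessages(site_differential_methylation(meth, groups)),
            "site_diff_methylation.tsv")
      }
      tsv(suppressMessages(site_expression_correlation(
        meth, expr, target, method = config$correlation_method)),
        "site_expression_correlation.tsv")
      target
    })
  } else {
    note("methylation", "SKIPPED", "methylation.tsv not present")
  }

  stages_tbl <- dplyr::bind_rows(stages)
  write_manifest(out_dir, config, stages_tbl)
  outputs$tmb <- tmb_groups
  outputs$tmb_degs <- tmb_degs
  outputs$model <- model_parts$model
  outputs$scores <- model_parts$scores
  outputs$cutoff <- model_parts$cutoff
  outputs$risk_degs <- risk_degs
  outputs$candidates <- candidates
  structure(list(stages = stages_tbl, outputs = outputs, out_dir = out_dir),
            class = "results_bundle")
}

write_manifest <- function(out_dir, config, stages) {
  jsonlite::write_json(list(
    package = "irgprog",
    version = as.character(utils::packageVersion("irgprog")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    files = list.files(out_dir, pattern = "\\.tsv$|\\.json$")
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("analysis bundle in", x$out_dir, "\n")
  print(x$stages)
  invisible(x)
}
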