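#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene symbols. Values are assumed to be on the
#' log2(normalized + 1) scale, though nothing downstream of the pair-indicator
#' construction depends on that choice. Duplicate gene rows are collapsed by
#' keeping the row with the largest mean (the drop is reported); duplicate
#' sample columns are an error.
#'
#' @param path Path to the TSV file.
#' @param strict If `TRUE` (default), any missing or non-numeric cell is an
#'   error naming the offending gene and sample. If `FALSE`, missing cells are
#'   mean-imputed per gene (row) with a warning.
#' @return A numeric matrix with genes as rows and samples as columns.
#' @export
read_expression <- function(path, strict = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample column")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw), dimnames = list(NULL, samples))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    if (strict) {
      stop(sprintf("non-numeric or missing expression value at gene '%s', sample '%s'",
                   genes[bad[1, 1]], samples[bad[1, 2]]))
    }
    warning(sprintf("%d missing expression value(s) mean-imputed per gene", nrow(bad)))
    for (i in unique(bad[, 1])) {
      row <- vals[i, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      vals[i, ] <- row
    }
  }
  rownames(vals) <- genes
  collapse_duplicate_genes(vals)
}

# keep, for each duplicated symbol, the row with the largest mean
collapse_duplicate_genes <- function(mat) {
  genes <- rownames(mat)
  if (!anyDuplicated(genes)) return(mat)
  dup <- unique(genes[duplicated(genes)])
  means <- rowMeans(mat)
  keep <- rep(TRUE, nrow(mat))
  for (g in dup) {
    idx <- which(genes == g)
    keep[idx] <- FALSE
    keep[idx[which.max(means[idx])]] <- TRUE
  }
  message(sprintf("collapsed %d duplicate gene row(s): %s (kept row with largest mean)",
                  sum(!keep), paste(dup, collapse = ", ")))
  mat[keep, , drop = FALSE]
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; the first column is named `gene`.
#'
#' @param expr Numeric gene x sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  out <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read somatic mutations from a MAF-style file
#'
#' Reads a tab-delimited Mutation Annotation Format file. Lines starting with
#' `#` are comments. The columns `Hugo_Symbol`, `Variant_Classification`,
#' `Variant_Type`, `Tumor_Sample_Barcode`, `Reference_Allele` and
#' `Tumor_Seq_Allele2` are required; `Chromosome` and `Start_Position` are
#' used when present. Unknown variant classifications are kept verbatim and
#' reported; filtering to nonsynonymous classes happens downstream in
#' [compute_tmb()].
#'
#' @param path Path to the MAF file.
#' @return A tibble of class `maf_tbl` with columns `sample`, `gene`,
#'   `variant_classification`, `variant_type`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("Hugo_Symbol", "Variant_Classification", "Variant_Type",
                "Tumor_Sample_Barcode", "Reference_Allele", "Tumor_Seq_Allele2")
  missing <- setdiff(required, colnames(raw))
  if (length(missing) > 0) {
    stop("MAF file is missing required column(s): ", paste(missing, collapse = ", "))
  }
  maf <- tibble::tibble(
    sample = raw$Tumor_Sample_Barcode,
    gene = raw$Hugo_Symbol,
    variant_classification = raw$Variant_Classification,
    variant_type = raw$Variant_Type,
    chromosome = if ("Chromosome" %in% colnames(raw)) raw$Chromosome else NA_character_,
    position = if ("Start_Position" %in% colnames(raw))
      as.integer(raw$Start_Position) else NA_integer_,
    ref_allele = raw$Reference_Allele,
    alt_allele = raw$Tumor_Seq_Allele2
  )
  validate_maf(maf)
  unknown <- setdiff(unique(maf$variant_classification), maf_known_classes())
  if (length(unknown) > 0) {
    message("MAF contains non-standard variant classification(s), kept verbatim: ",
            paste(unknown, collapse = ", "))
  }
  class(maf) <- c("maf_tbl", class(maf))
  maf
}

#' Write a mutation table to a MAF-style file
#'
#' @param maf A tibble as returned by [read_maf()] or [simulate_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  validate_maf(maf)
  out <- tibble::tibble(
    Hugo_Symbol = maf$gene,
    Chromosome = maf$chromosome,
    Start_Position = maf$position,
    Variant_Classification = maf$variant_classification,
    Variant_Type = maf$variant_type,
    Reference_Allele = maf$ref_allele,
    Tumor_Seq_Allele2 = maf$alt_allele,
    Tumor_Sample_Barcode = maf$sample
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

maf_known_classes <- function() {
  c(nonsynonymous_classes(),
    "Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
    "Targeted_Region")
}

validate_maf <- function(maf) {
  needed <- c("sample", "gene", "variant_classification", "variant_type",
              "ref_allele", "alt_allele")
  missing <- setdiff(needed, colnames(maf))
  if (length(missing) > 0) stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!nzchar(maf$sample) | is.na(maf$sample))) stop("mutation record with empty sample id")
  if (any(!nzchar(maf$gene) | is.na(maf$gene))) stop("mutation record with empty gene symbol")
  bad_type <- setdiff(unique(maf$variant_type), c("SNP", "DEL", "INS"))
  if (length(bad_type) > 0) {
    stop("variant_type must be SNP, DEL or INS; found: ", paste(bad_type, collapse = ", "))
  }
  if ("position" %in% colnames(maf) && any(!is.na(maf$position) & maf$position < 1)) {
    stop("variant position must be >= 1")
  }
  invisible(maf)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample`, `os_time` (overall-survival time in days) and
#' `os_event` (1 = death observed, 0 = censored). Optional covariate columns
#' (`age`, `stage`, `t_stage`, `grade`, `gender`) are carried through when
#' present.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per sample.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  # numeric conversion through base strtod so written doubles round-trip
  for (v in intersect(c("os_time", "os_event", "age"), colnames(tbl))) {
    tbl[[v]] <- as.numeric(tbl[[v]])
  }
  validate_clinical(tbl)
  tbl
}

validate_clinical <- function(tbl) {
  missing <- setdiff(c("sample", "os_time", "os_event"), colnames(tbl))
  if (length(missing) > 0) stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tbl$sample)) {
    stop("duplicate clinical sample id(s): ",
         paste(unique(tbl$sample[duplicated(tbl$sample)]), collapse = ", "))
  }
  if (any(is.na(tbl$os_time)) || any(tbl$os_time < 0)) stop("os_time must be >= 0 days")
  if (!all(tbl$os_event %in% c(0, 1))) stop("os_event must be 0 (censored) or 1 (death)")
  invisible(tbl)
}

#' Write a clinical table to TSV
#' @param clinical Tibble with at least `sample`, `os_time`, `os_event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Read a CpG methylation beta matrix plus its probe-to-gene map
#'
#' The beta file follows the expression layout (first column `probe`, one
#' column per sample); the map file has columns `probe` and `gene`. Beta
#' values must lie in \[0, 1\]; missing values are allowed and counted in a
#' warning, values outside the unit interval are an error naming the probe
#' and sample.
#'
#' @param path Path to the beta-value TSV.
#' @param map_path Path to the probe-to-gene map TSV.
#' @return A list of class `meth_set` with elements `beta` (probe x sample
#'   numeric matrix) and `probe_map` (tibble `probe`, `gene`).
#' @export
read_methylation <- function(path, map_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  probes <- raw[[1]]
  if (anyDuplicated(probes)) {
    stop("duplicate probe id(s): ", paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  beta <- vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = nrow(raw), dimnames = list(NULL, colnames(raw)[-1]))
  rownames(beta) <- probes
  map <- readr::read_tsv(map_path, col_types = readr::cols(probe = "c", gene = "c"),
                         progress = FALSE)
  meth_set(beta, map)
}

#' Construct and validate a methylation set
#'
#' @param beta Probe x sample numeric matrix of beta values in \[0, 1\].
#' @param probe_map Tibble with columns `probe` and `gene`.
#' @return A list of class `meth_set`.
#' @export
meth_set <- function(beta, probe_map) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  out_of_range <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s'",
                 rownames(beta)[out_of_range[1, 1]],
                 colnames(beta)[out_of_range[1, 2]]))
  }
  n_missing <- sum(is.na(beta))
  if (n_missing > 0) warning(sprintf("%d missing beta value(s) in methylation matrix", n_missing))
  missing_cols <- setdiff(c("probe", "gene"), colnames(probe_map))
  if (length(missing_cols) > 0) {
    stop("probe map lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  structure(list(beta = beta, probe_map = tibble::as_tibble(probe_map)),
            class = "meth_set")
}

#' Write a methylation set to TSV files
#' @param meth A `meth_set`.
#' @param path Output path for the beta matrix.
#' @param map_path Output path for the probe-to-gene map.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(meth, path, map_path) {
  out <- tibble::as_tibble(meth$beta, rownames = "probe")
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(meth$probe_map, map_path, progress = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and surrounding whitespace are dropped; duplicates are removed
#' keeping the first occurrence.
#'
#' @param path Path to the text file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Intersect sample ids across analysis inputs
#'
#' Analyses run on the samples present in every required input; ids missing
#' from any input are dropped with a message (TCGA-style barcodes commonly
#' differ in coverage across assays).
#'
#' @param ... Character vectors of sample ids.
#' @return Character vector: the intersection, in the order of the first
#'   argument.
#' @export
common_samples <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  keep <- Reduce(intersect, sets)
  keep <- sets[[1]][sets[[1]] %in% keep]
  dropped <- setdiff(unique(unlist(sets)), keep)
  if (length(dropped) > 0) {
    message(sprintf("dropping %d sample(s) absent from at least one input", length(dropped)))
  }
  keep
}

#' Analysis run configuration
#'
#' Collects every tunable threshold used across the pipeline with its
#' documented default, so that a run can be serialized and reproduced.
#'
#' @param exome_mb Size in megabases of the interrogated exome used as the
#'   TMB denominator (default 38, a common exome-capture convention).
#' @param nonsyn_only Count only nonsynonymous variant classes in TMB.
#' @param min_pair_freq Balance-filter bound for pair indicators: retain pairs
#'   with indicator frequency in `[min_pair_freq, 1 - min_pair_freq]`.
#' @param screen_p Univariate Cox screening p-value threshold.
#' @param cv_folds Cross-validation folds for penalized Cox fits.
#' @param model_method `"lasso"` or `"stepwise"` multivariate selection.
#' @param horizon_days Survival-ROC horizon in days (1825 = 5 years).
#' @param fdr_threshold Benjamini-Hochberg FDR threshold for DEG calls.
#' @param logfc_threshold Minimum absolute log2 fold change for DEG calls.
#' @param correlation_method `"pearson"` or `"spearman"` for site-expression
#'   correlation.
#' @param seed Integer seed controlling all randomized steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(exome_mb = 38, nonsyn_only = TRUE, min_pair_freq = 0.2,
                       screen_p = 0.01, cv_folds = 10, model_method = "lasso",
                       horizon_days = 1825, fdr_threshold = 0.05,
                       logfc_threshold = 0, correlation_method = "pearson",
                       seed = 1L) {
  stopifnot(exome_mb > 0, min_pair_freq > 0, min_pair_freq < 0.5,
            screen_p > 0, screen_p <= 1, cv_folds >= 3, horizon_days > 0)
  model_method <- match.arg(model_method, c("lasso", "stepwise"))
  correlation_method <- match.arg(correlation_method, c("pearson", "spearman"))
  structure(list(
    exome_mb = exome_mb, nonsyn_only = nonsyn_only,
    min_pair_freq = min_pair_freq, screen_p = screen_p, cv_folds = cv_folds,
    model_method = model_method, horizon_days = horizon_days,
    fdr_threshold = fdr_threshold, logfc_threshold = logfc_threshold,
    correlation_method = correlation_method, seed = as.integer(seed)
  ), class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fields absent from the file keep their [run_config()] defaults.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}
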