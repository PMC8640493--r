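#' Read a gene-by-sample expression TSV
#'
#' Dialect: tab-separated, header row with the gene-id column name followed
#' by one sample id per column; one row per gene with the gene id first.
#' Parsing is strict: ragged rows, duplicate gene or sample ids, non-numeric
#' or missing cells and negative values are all rejected with errors naming
#' the offending line — silent coercion to `NA` would corrupt downstream
#' indicators, which are undefined on missingness.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("expression file needs a header and at least one gene row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row at line %d: %d field(s), expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  if (nf[1] < 2) stop("no sample columns found", call. = FALSE)
  samples <- fields[[1]][-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  genes <- vapply(fields[-1], `[`, "", 1)
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    vals <- suppressWarnings(as.numeric(fields[[i + 1]][-1]))
    if (anyNA(vals))
      stop(sprintf("non-numeric or missing cell at line %d (gene %s)",
                   i + 1, genes[i]), call. = FALSE)
    m[i, ] <- vals
  }
  if (any(m < 0))
    stop("negative expression value(s) found; expression must be nonnegative",
         call. = FALSE)
  m
}

#' @rdname read_expression
#' @param expression Matrix to write (gene rownames, sample colnames).
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLINICAL_COLUMNS <- c("sample_id", "pfs_months", "event", "response",
                      "pdl1", "pathology", "sex")

#' Read a clinical CSV
#'
#' Dialect: comma-separated with header
#' `sample_id,pfs_months,event,response,pdl1,pathology,sex`. Validation is
#' row-level and strict: `pfs_months` must be a positive number, `event`
#' must be 0 or 1, `response` must be one of the four RECIST categories
#' (CR, PR, SD, PD), `pdl1` one of high/low, and sample ids unique.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the validated columns (`pfs_months` numeric,
#'   `event` integer, the rest character).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  miss <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(miss))
    stop("clinical file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  pfs <- suppressWarnings(as.numeric(df$pfs_months))
  bad <- which(is.na(pfs) | pfs <= 0)
  if (length(bad))
    stop(sprintf("invalid pfs_months at data row %d (must be a positive number)",
                 bad[1]), call. = FALSE)
  ev <- suppressWarnings(as.numeric(df$event))
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("invalid event at data row %d (must be 0 or 1)", bad[1]),
         call. = FALSE)
  bad <- which(!(df$response %in% c("CR", "PR", "SD", "PD")))
  if (length(bad))
    stop(sprintf("unknown response label '%s' at data row %d (allowed: CR, PR, SD, PD)",
                 df$response[bad[1]], bad[1]), call. = FALSE)
  bad <- which(!(df$pdl1 %in% c("high", "low")))
  if (length(bad))
    stop(sprintf("unknown pdl1 label '%s' at data row %d (allowed: high, low)",
                 df$pdl1[bad[1]], bad[1]), call. = FALSE)
  df$pfs_months <- pfs
  df$event <- as.integer(ev)
  df[, CLINICAL_COLUMNS]
}

#' @rdname read_clinical
#' @param clinical Data frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical[, CLINICAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Align an expression matrix with a clinical table by sample id
#'
#' Matching is always by id, never by position. When the two id sets
#' differ, the error reports the symmetric difference explicitly.
#'
#' @param expression Gene-by-sample matrix with sample colnames.
#' @param clinical Data frame with a `sample_id` column.
#' @return List with the expression columns reordered to the clinical rows.
#' @export
align_cohort <- function(expression, clinical) {
  es <- colnames(expression)
  cs <- clinical$sample_id
  if (is.null(es)) stop("expression matrix has no sample ids", call. = FALSE)
  only_e <- setdiff(es, cs)
  only_c <- setdiff(cs, es)
  if (length(only_e) || length(only_c))
    stop("sample id mismatch between expression and clinical data\n",
         "  only in expression: ",
         if (length(only_e)) paste(only_e, collapse = ", ") else "(none)", "\n",
         "  only in clinical:   ",
         if (length(only_c)) paste(only_c, collapse = ", ") else "(none)",
         call. = FALSE)
  list(expression = expression[, cs, drop = FALSE], clinical = clinical)
}

#' Read a cohort from an expression TSV and a clinical CSV
#'
#' @param expression_path,clinical_path File paths in the package dialects.
#' @return A `brgpi_cohort`-like list (without simulation truth).
#' @export
read_cohort <- function(expression_path, clinical_path) {
  expr <- read_expression(expression_path)
  cl <- read_clinical(clinical_path)
  aligned <- align_cohort(expr, cl)
  structure(list(expression = aligned$expression,
                 gene_ids = rownames(expr),
                 sample_ids = aligned$clinical$sample_id,
                 clinical = aligned$clinical),
            class = "brgpi_cohort")
}

#' Read a simulation configuration from a YAML/JSON key-value file
#'
#' Keys mirror the [sim_config()] arguments; `planted_pairs` is a list of
#' `{gene_a, gene_b, beta}` entries.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return A `brgpi_sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$planted_pairs)) {
    pp <- cfg$planted_pairs
    cfg$planted_pairs <- data.frame(
      gene_a = vapply(pp, function(p) as.character(p$gene_a), ""),
      gene_b = vapply(pp, function(p) as.character(p$gene_b), ""),
      beta = vapply(pp, function(p) as.numeric(p$beta), 0),
      stringsAsFactors = FALSE)
  }
  do.call(sim_config, cfg)
}

# drop non-serializable members and flatten classed stats objects;
# infinite medians ("not reached") become JSON null
report_to_list <- function(report) {
  lr_list <- function(lr) if (is.null(lr)) NULL else
    list(statistic = lr$statistic, df = lr$df, p = lr$p)
  fin <- function(x) as.list(ifelse(is.finite(x), x, NA_real_))
  list(n = report$n,
       n_events = report$n_events,
       horizon_months = report$horizon_months,
       cutoff = report$cutoff,
       group_sizes = as.list(report$group_sizes),
       auc = report$auc,
       optimal_cutoff = report$roc$optimal_cutoff,
       logrank = lr_list(report$logrank),
       median_pfs = fin(report$median_pfs),
       cox_univariate = report$cox_univariate,
       cox_multivariate = report$cox_multivariate,
       response_score_medians = as.list(report$response_score_medians),
       response_tests = report$response_tests,
       pdl1_combined = if (is.null(report$pdl1_combined)) NULL else list(
         n = as.list(report$pdl1_combined$n),
         median_pfs = fin(report$pdl1_combined$median_pfs),
         logrank = lr_list(report$pdl1_combined$logrank),
         n_excluded = report$pdl1_combined$n_excluded),
       warnings = report$warnings)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `brgpi_report` from [evaluate_cohort()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "brgpi_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null",
                       force = TRUE)
  invisible(path)
}
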