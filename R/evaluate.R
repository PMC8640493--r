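#' Score samples with a gene-pair signature
#'
#' The index of a sample is the coefficient-weighted sum of its pair
#' indicators: `score = sum_k coef_k * indicator_k`. The score is linear in
#' the indicators, so switching one indicator from 0 to 1 changes the score
#' by exactly that pair's coefficient.
#'
#' @param indicators A `brgpi_pairs` object containing every model pair.
#' @param model A `brgpi_signature`.
#' @return Named numeric vector of per-sample scores.
#' @export
score_brgpi <- function(indicators, model) {
  stopifnot(inherits(indicators, "brgpi_pairs"),
            inherits(model, "brgpi_signature"))
  miss <- setdiff(model$pairs$pair_id, rownames(indicators$values))
  if (length(miss))
    stop("signature pair(s) missing from indicators: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- indicators$values[model$pairs$pair_id, , drop = FALSE]
  stats::setNames(colSums(v * unname(model$coefficients)),
                  indicators$sample_ids)
}

#' Dichotomize index scores at a cutoff
#'
#' A sample is `"high"` iff its score is strictly above the cutoff; a score
#' exactly equal to the cutoff is `"low"` (fixed boundary convention).
#'
#' @param scores Numeric scores.
#' @param cutoff Finite cutoff.
#' @return Factor with levels `c("low", "high")`, names preserved.
#' @export
classify <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  stats::setNames(factor(ifelse(scores > cutoff, "high", "low"),
                         levels = c("low", "high")),
                  names(scores))
}

cox_term_row <- function(time, event, x, term) {
  f <- tryCatch(fit_cox(time, event, x),
                error = function(e) NULL)
  if (is.null(f))
    return(data.frame(term = term, beta = NA_real_, se = NA_real_,
                      hazard_ratio = NA_real_, p = NA_real_))
  data.frame(term = term, beta = unname(f$coefficients[1]),
             se = unname(f$standard_errors[1]),
             hazard_ratio = unname(f$hazard_ratios[1]),
             p = unname(f$wald_p[1]))
}

#' Full evaluation of a signature on one cohort
#'
#' Runs the standard evaluation battery for a frozen signature on a cohort:
#' time-dependent ROC AUC at the model horizon; Kaplan-Meier curves and
#' log-rank test for index-low vs index-high; univariate Cox fits of the
#' binary index group and each clinical covariate plus a multivariate fit
#' adjusting the index for sex and pathology; and nonparametric comparisons
#' of the score across response groupings — Kruskal-Wallis over CR/PR vs SD
#' vs PD, Mann-Whitney for response (CR/PR) vs non-response (SD/PD), and
#' Mann-Whitney for PD vs non-PD (non-PD = CR, PR or SD). Degenerate
#' groupings (an empty index group, a single response category) are skipped
#' with a warning and recorded in the report rather than raising errors.
#'
#' @param cohort A `brgpi_cohort`, or a list with `expression` and
#'   `clinical` components in the package's dialects.
#' @param model A `brgpi_signature` with a finite cutoff.
#' @return Object of class `brgpi_report` (a structured list; see
#'   [write_report()] for serialization).
#' @export
evaluate_cohort <- function(cohort, model) {
  stopifnot(inherits(model, "brgpi_signature"))
  if (!is.finite(model$cutoff))
    stop("model has no cutoff; set one (e.g. via td_roc) before evaluation",
         call. = FALSE)
  cl <- cohort$clinical
  time <- cl$pfs_months
  event <- cl$event
  ind <- encode_pairs(cohort$expression, model$pairs)
  scores <- score_brgpi(ind, model)
  grp <- classify(scores, model$cutoff)

  roc <- td_roc(scores, time, event, model$horizon_months)

  warnings_log <- character(0)
  both_groups <- all(c("low", "high") %in% grp)
  if (both_groups) {
    lr <- logrank_test(grp, time, event)
    km <- lapply(split(seq_along(time), grp),
                 function(i) km_estimate(time[i], event[i]))
    med <- vapply(km, median_survival, 0)
  } else {
    msg <- "one index group is empty after classification; log-rank skipped"
    warning(msg, call. = FALSE)
    warnings_log <- c(warnings_log, msg)
    lr <- NULL
    km <- lapply(split(seq_along(time), grp, drop = TRUE),
                 function(i) km_estimate(time[i], event[i]))
    med <- vapply(km, median_survival, 0)
  }

  high <- as.numeric(grp == "high")
  male <- as.numeric(cl$sex == "male")
  squam <- as.numeric(cl$pathology == "squamous")
  pdl1h <- as.numeric(cl$pdl1 == "high")
  uni <- rbind(cox_term_row(time, event, high, "index_high"),
               cox_term_row(time, event, male, "sex_male"),
               cox_term_row(time, event, squam, "pathology_squamous"),
               cox_term_row(time, event, pdl1h, "pdl1_high"))
  mv <- tryCatch({
    f <- fit_cox(time, event,
                 cbind(index_high = high, sex_male = male,
                       pathology_squamous = squam))
    data.frame(term = names(f$coefficients), beta = unname(f$coefficients),
               se = unname(f$standard_errors),
               hazard_ratio = unname(f$hazard_ratios),
               p = unname(f$wald_p))
  }, error = function(e) {
    warnings_log <<- c(warnings_log,
                       paste("multivariate Cox skipped:", conditionMessage(e)))
    NULL
  })

  resp <- factor(cl$response, levels = c("CR", "PR", "SD", "PD"))
  g3 <- factor(ifelse(resp %in% c("CR", "PR"), "CR/PR", as.character(resp)),
               levels = c("CR/PR", "SD", "PD"))
  g3 <- droplevels(g3)
  score_medians <- tapply(scores, g3, stats::median)
  resp_tests <- list()
  if (nlevels(g3) >= 2) {
    kw <- stats::kruskal.test(scores, g3)
    resp_tests$kruskal_crpr_sd_pd <- list(statistic = unname(kw$statistic),
                                          df = unname(kw$parameter),
                                          p = kw$p.value)
  } else {
    msg <- "response grouping degenerate (single category); tests skipped"
    warning(msg, call. = FALSE)
    warnings_log <- c(warnings_log, msg)
  }
  two_group_test <- function(flag, name) {
    if (length(unique(flag)) == 2) {
      wt <- stats::wilcox.test(scores[flag], scores[!flag], exact = FALSE)
      resp_tests[[name]] <<- list(statistic = unname(wt$statistic),
                                  p = wt$p.value)
    }
  }
  two_group_test(resp %in% c("CR", "PR"), "response_vs_nonresponse")
  two_group_test(resp == "PD", "pd_vs_nonpd")

  pdl1_combined <- if (both_groups && length(unique(cl$pdl1)) > 1)
    tryCatch(pdl1_combined_groups(cohort, model),
             error = function(e) NULL, warning = function(w) NULL)
  else NULL

  structure(list(n = length(time),
                 n_events = sum(event),
                 horizon_months = model$horizon_months,
                 cutoff = model$cutoff,
                 scores = scores,
                 groups = grp,
                 group_sizes = table(grp),
                 auc = roc$auc,
                 roc = roc,
                 logrank = lr,
                 km = km,
                 median_pfs = med,
                 cox_univariate = uni,
                 cox_multivariate = mv,
                 response_score_medians = score_medians,
                 response_tests = resp_tests,
                 pdl1_combined = pdl1_combined,
                 warnings = warnings_log),
            class = "brgpi_report")
}

#' @export
print.brgpi_report <- function(x, ...) {
  cat(sprintf("Cohort evaluation (n = %d, %d events)\n", x$n, x$n_events))
  cat(sprintf("  index groups: low = %d, high = %d (cutoff %.4g)\n",
              x$group_sizes["low"], x$group_sizes["high"], x$cutoff))
  cat(sprintf("  AUC at %g months: %.3f\n", x$horizon_months, x$auc))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank low vs high: chisq = %.3g, p = %.3g\n",
                x$logrank$statistic, x$logrank$p))
  if (!is.null(x$response_tests$kruskal_crpr_sd_pd))
    cat(sprintf("  score vs response (CR/PR, SD, PD): Kruskal-Wallis p = %.3g\n",
                x$response_tests$kruskal_crpr_sd_pd$p))
  if (!is.null(x$pdl1_combined))
    cat(sprintf("  index x PD-L1 three-group log-rank p = %.3g\n",
                x$pdl1_combined$logrank$p))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Kaplan-Meier / log-rank comparison of index groups within strata
#'
#' Within each level of a stratification variable (pathology or PD-L1),
#' compares index-low vs index-high PFS by log-rank. A stratum in which only
#' one index group is present (or that has no events) is reported as
#' non-testable rather than dropped silently; empty strata are omitted.
#'
#' @param cohort A `brgpi_cohort`-like list.
#' @param model A `brgpi_signature` with a finite cutoff.
#' @param stratum_field `"pathology"` or `"pdl1"`.
#' @return Data frame with one row per stratum: group sizes, median PFS per
#'   group, log-rank statistic and p, and a `testable` flag.
#' @export
stratified_km <- function(cohort, model,
                          stratum_field = c("pathology", "pdl1")) {
  stratum_field <- match.arg(stratum_field)
  cl <- cohort$clinical
  if (!stratum_field %in% names(cl))
    stop("stratum field not present in clinical data", call. = FALSE)
  ind <- encode_pairs(cohort$expression, model$pairs)
  grp <- classify(score_brgpi(ind, model), model$cutoff)
  out <- lapply(unique(cl[[stratum_field]]), function(lv) {
    i <- which(cl[[stratum_field]] == lv)
    if (!length(i)) return(NULL)
    gi <- droplevels(grp[i])
    testable <- nlevels(gi) == 2 && sum(cl$event[i]) >= 1
    med <- function(g) {
      j <- i[grp[i] == g]
      if (length(j)) median_survival(km_estimate(cl$pfs_months[j],
                                                 cl$event[j])) else NA_real_
    }
    if (testable) {
      lr <- logrank_test(grp[i], cl$pfs_months[i], cl$event[i])
      data.frame(stratum = lv, n = length(i),
                 n_low = sum(grp[i] == "low"), n_high = sum(grp[i] == "high"),
                 median_low = med("low"), median_high = med("high"),
                 statistic = lr$statistic, p = lr$p, testable = TRUE)
    } else {
      data.frame(stratum = lv, n = length(i),
                 n_low = sum(grp[i] == "low"), n_high = sum(grp[i] == "high"),
                 median_low = med("low"), median_high = med("high"),
                 statistic = NA_real_, p = NA_real_, testable = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Combined index x PD-L1 three-group analysis
#'
#' Calls a sample's status favorable on the index when it is index-low and
#' favorable on PD-L1 when it is PD-L1-high, and assigns each sample to one
#' of three groups: both favorable (index-low and PD-L1-high), exactly one
#' favorable (index-low or PD-L1-high but not both), neither favorable
#' (index-high and PD-L1-low). Reports the overall log-rank test across the
#' groups present and per-group median PFS. Samples with missing PD-L1 are
#' excluded and counted.
#'
#' @param cohort A `brgpi_cohort`-like list with a `pdl1` clinical column.
#' @param model A `brgpi_signature` with a finite cutoff.
#' @return List with `labels` (factor per retained sample, levels
#'   `both_favorable`, `one_favorable`, `neither_favorable`), `n` per group,
#'   `median_pfs` per group, `logrank`, and `n_excluded`.
#' @export
pdl1_combined_groups <- function(cohort, model) {
  cl <- cohort$clinical
  if (!"pdl1" %in% names(cl))
    stop("PD-L1 labels are required", call. = FALSE)
  ind <- encode_pairs(cohort$expression, model$pairs)
  grp <- classify(score_brgpi(ind, model), model$cutoff)
  keep <- !is.na(cl$pdl1) & cl$pdl1 %in% c("high", "low")
  n_excluded <- sum(!keep)
  if (n_excluded)
    warning(n_excluded, " sample(s) excluded for missing PD-L1", call. = FALSE)
  fav <- (grp[keep] == "low") + (cl$pdl1[keep] == "high")
  labels <- factor(c("neither_favorable", "one_favorable",
                     "both_favorable")[fav + 1],
                   levels = c("both_favorable", "one_favorable",
                              "neither_favorable"))
  present <- droplevels(labels)
  if (nlevels(present) < 2)
    stop("fewer than two combined groups present; log-rank undefined",
         call. = FALSE)
  lr <- logrank_test(present, cl$pfs_months[keep], cl$event[keep])
  med <- vapply(levels(labels), function(lv) {
    i <- which(labels == lv)
    if (length(i))
      median_survival(km_estimate(cl$pfs_months[keep][i], cl$event[keep][i]))
    else NA_real_
  }, 0)
  list(labels = labels,
       n = table(labels),
       median_pfs = med,
       logrank = lr,
       n_excluded = n_excluded)
}

#' Plot Kaplan-Meier curves of the index groups in a report
#'
#' @param x A `brgpi_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.brgpi_report <- function(x, ...) {
  cols <- c(low = "#2166AC", high = "#B2182B")
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$km, `[[`, "time")))),
                 ylim = c(0, 1), xlab = "Months", ylab = "PFS probability",
                 main = "Kaplan-Meier by index group", ...)
  for (g in names(x$km)) {
    km <- x$km[[g]]
    graphics::lines(stats::stepfun(km$time, c(1, km$survival)),
                    do.points = FALSE, col = cols[[g]])
  }
  graphics::legend("topright", legend = names(x$km), col = cols[names(x$km)],
                   lty = 1, bty = "n")
  invisible(x)
}
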