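#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron correction for tied event
#' times by default) and returns coefficients, standard errors from the
#' observed information, hazard ratios, and two-sided Wald p-values.
#' Degenerate inputs are handled explicitly rather than propagated:
#' a covariate with no contrast (constant across subjects) gets coefficient
#' 0, infinite standard error and p = 1; a monotone likelihood (perfect
#' separation, common for binary indicators on tiny cohorts) is detected,
#' the coefficient is capped at |beta| = 15 and the fit is flagged
#' non-converged instead of silently diverging.
#'
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicators; at least one event is required.
#' @param x Covariate vector or sample-by-feature matrix.
#' @param ties `"efron"` (default) or `"breslow"` tie correction.
#' @return Object of class `brgpi_coxfit`: list with `coefficients`,
#'   `standard_errors`, `hazard_ratios`, `wald_p`, `log_partial_likelihood`,
#'   `null_log_partial_likelihood`, `df`, `converged`, `n`, `n_events`.
#' @export
#' @examples
#' fit <- fit_cox(c(2, 4, 3, 7, 9, 1), c(1, 1, 0, 1, 0, 1), c(1, 1, 0, 0, 0, 1))
#' fit$hazard_ratios
fit_cox <- function(time, event, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(time)
  if (length(event) != n || nrow(x) != n)
    stop("time, event and covariates must have matching lengths", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be positive and finite", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be coded 0/1", call. = FALSE)
  if (sum(event) < 1)
    stop("at least one event is required to fit a Cox model", call. = FALSE)

  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(x, survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(iter.max = 100L,
                                                          eps = 1e-9),
                        weights = NULL, method = ties, rownames = NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })

  beta <- fit$coefficients
  vr <- as.matrix(fit$var)
  se <- sqrt(pmax(diag(vr), 0))
  singular <- is.na(beta)
  beta[singular] <- 0
  se[singular] <- Inf
  converged <- !warned && fit$iter < 100L
  capped <- !singular & abs(beta) > 15
  if (any(capped)) {
    beta[capped] <- sign(beta[capped]) * 15
    converged <- FALSE
  }
  z <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[singular] <- 1
  ll <- fit$loglik[length(fit$loglik)]
  nms <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  names(beta) <- names(se) <- names(p) <- nms
  structure(list(coefficients = beta,
                 standard_errors = se,
                 hazard_ratios = exp(beta),
                 wald_p = p,
                 log_partial_likelihood = ll,
                 null_log_partial_likelihood = fit$loglik[1],
                 df = sum(!singular),
                 iterations = fit$iter,
                 converged = converged,
                 n = n, n_events = sum(event),
                 ties = ties),
            class = "brgpi_coxfit")
}

#' @export
print.brgpi_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d%s\n", x$ties, x$n,
              x$n_events, if (x$converged) "" else "  [NOT converged]"))
  print(data.frame(coef = x$coefficients, se = x$standard_errors,
                   HR = x$hazard_ratios, p = x$wald_p))
  invisible(x)
}

#' @export
coef.brgpi_coxfit <- function(object, ...) object$coefficients

# AIC on the partial likelihood, counting only estimable coefficients.
cox_aic <- function(fit) -2 * fit$log_partial_likelihood + 2 * fit$df

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects leave the risk set at their censoring time without a
#' drop in the survival curve; with no censoring the estimate reduces to the
#' complement of the empirical distribution function.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return Object of class `brgpi_km`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty survival data", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, survival = sf$surv),
            class = "brgpi_km")
}

#' @export
print.brgpi_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median = %s months\n",
              length(x$time),
              format(median_survival(x), digits = 4)))
  invisible(x)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' First time at which the survival estimate drops to 0.5 or below; `Inf`
#' when the curve never reaches 0.5.
#'
#' @param km A `brgpi_km` object.
#' @return Median time (months), possibly `Inf`.
#' @export
median_survival <- function(km) {
  i <- which(km$survival <= 0.5)
  if (length(i)) km$time[min(i)] else Inf
}

#' Log-rank test for equality of survival across groups
#'
#' Standard observed-minus-expected log-rank chi-square with `k - 1` degrees
#' of freedom for `k` groups; the p-value is the upper chi-square tail.
#'
#' @param group Group labels (coerced to factor); every level must be
#'   non-empty and at least two groups are required.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (at least one event overall).
#' @return Object of class `brgpi_logrank`: list with `statistic`, `df`,
#'   `p`, per-group `n`, `observed` and `expected` event counts.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(group) < 2)
    stop("log-rank test requires at least two groups", call. = FALSE)
  tab <- table(group)
  if (any(tab == 0))
    stop("empty group(s): ", paste(names(tab)[tab == 0], collapse = ", "),
         call. = FALSE)
  if (sum(event) < 1)
    stop("at least one event is required", call. = FALSE)
  d <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- nlevels(group) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = as.vector(tab), groups = names(tab),
                 observed = as.vector(sd$obs), expected = as.vector(sd$exp)),
            class = "brgpi_logrank")
}

#' @export
print.brgpi_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}
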