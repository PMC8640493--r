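#' Univariate Cox screen of pair indicators
#'
#' Fits one univariate Cox model per pair indicator against PFS and returns
#' the pairs with two-sided Wald p below `alpha`, sorted by p ascending.
#' No multiple-testing correction is applied by default — this deliberately
#' reproduces the raw per-pair "P < 0.05" screen conventional in this
#' signature literature; set `adjust = "BH"` for a Benjamini-Hochberg
#' variant (a documented deviation from that convention). Constant indicator
#' rows carry no contrast and are skipped with a warning rather than an
#' error.
#'
#' @param indicators A `brgpi_pairs` object.
#' @param time,event Survival outcome aligned with `indicators$sample_ids`.
#' @param alpha Screening level in `(0, 1]`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param ties Tie correction passed to [fit_cox()].
#' @return A data frame of class `brgpi_screen` with columns `pair_id`,
#'   `gene_a`, `gene_b`, `beta`, `se`, `hazard_ratio`, `p`, sorted by `p`;
#'   attributes `alpha`, `n_tested`, `n_skipped`.
#' @export
screen_pairs <- function(indicators, time, event, alpha = 0.05,
                         adjust = c("none", "BH"), ties = "efron") {
  stopifnot(inherits(indicators, "brgpi_pairs"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  v <- indicators$values
  if (ncol(v) != length(time))
    stop("indicators and survival data must cover the same samples",
         call. = FALSE)
  m <- rowMeans(v)
  const <- m <= 0 | m >= 1
  if (any(const))
    warning(sum(const), " constant pair indicator(s) skipped (no contrast)",
            call. = FALSE)
  rows <- which(!const)
  beta <- se <- p <- numeric(length(rows))
  for (i in seq_along(rows)) {
    f <- fit_cox(time, event, v[rows[i], ], ties = ties)
    beta[i] <- f$coefficients
    se[i] <- f$standard_errors
    p[i] <- f$wald_p
  }
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  out <- data.frame(pair_id = indicators$pairs$pair_id[rows],
                    gene_a = indicators$pairs$gene_a[rows],
                    gene_b = indicators$pairs$gene_b[rows],
                    beta = beta, se = se, hazard_ratio = exp(beta), p = p,
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- length(rows)
  attr(out, "n_skipped") <- sum(const)
  class(out) <- c("brgpi_screen", "data.frame")
  out
}

#' Forward stepwise multivariate Cox selection of a pair signature
#'
#' Starting from the empty model, repeatedly adds the candidate pair whose
#' inclusion most decreases the AIC of the joint multivariate Cox fit,
#' stopping when no addition improves the AIC or when `k_max` pairs are
#' included. The coefficients of the final joint fit become the signature
#' weights. The procedure is deterministic given identical inputs. If no
#' single candidate improves on the null model, the best-p candidate is
#' returned alone with its univariate coefficient (with a warning).
#'
#' @param candidates A `brgpi_screen` data frame (or any data frame with
#'   `pair_id`, `gene_a`, `gene_b`, `p` columns), typically from
#'   [screen_pairs()].
#' @param indicators The `brgpi_pairs` object the candidates refer to.
#' @param time,event Survival outcome.
#' @param k_max Maximum signature size (default 4).
#' @param horizon_months ROC horizon stored on the returned model.
#' @param ties Tie correction passed to [fit_cox()].
#' @return A `brgpi_signature` with unset cutoff; the final joint
#'   `brgpi_coxfit` is attached as `$fit` and the AIC trace as `$aic_trace`.
#' @export
select_signature <- function(candidates, indicators, time, event,
                             k_max = 4, horizon_months = 12, ties = "efron") {
  if (!nrow(candidates)) stop("no candidate pairs supplied", call. = FALSE)
  candidates <- candidates[order(candidates$p), , drop = FALSE]
  X <- t(indicators$values[candidates$pair_id, , drop = FALSE])
  null_aic <- {
    f0 <- fit_cox(time, event, X[, 1], ties = ties)
    -2 * f0$null_log_partial_likelihood
  }
  selected <- integer(0)
  cur_aic <- null_aic
  final_fit <- NULL
  trace <- numeric(0)
  repeat {
    rem <- setdiff(seq_len(ncol(X)), selected)
    if (!length(rem) || length(selected) >= k_max) break
    best_j <- 0L
    best_aic <- cur_aic
    best_fit <- NULL
    for (j in rem) {
      xj <- X[, c(selected, j), drop = FALSE]
      f <- fit_cox(time, event, xj, ties = ties)
      a <- cox_aic(f)
      if (a < best_aic - 1e-9) {
        best_aic <- a
        best_j <- j
        best_fit <- f
      }
    }
    if (best_j == 0L) break
    selected <- c(selected, best_j)
    cur_aic <- best_aic
    final_fit <- best_fit
    trace <- c(trace, best_aic)
  }
  if (!length(selected)) {
    warning("no pair improved the AIC over the null model; ",
            "returning the best-p candidate with its univariate coefficient",
            call. = FALSE)
    selected <- 1L
    final_fit <- fit_cox(time, event, X[, 1, drop = FALSE], ties = ties)
    trace <- cox_aic(final_fit)
  }
  sel <- candidates[selected, , drop = FALSE]
  sig <- new_brgpi_signature(
    pairs = sel[, c("gene_a", "gene_b", "pair_id")],
    coefficients = unname(final_fit$coefficients),
    cutoff = NA_real_,
    horizon_months = horizon_months,
    provenance = sprintf("forward stepwise AIC selection (%d of %d candidates)",
                         length(selected), nrow(candidates)))
  sig$fit <- final_fit
  sig$aic_trace <- c(null = null_aic, trace)
  sig
}

#' Fit a gene-pair index to an expression + survival cohort
#'
#' The full signature construction in one call: build all pairs from the
#' panel genes present in the expression matrix, encode within-sample
#' relative-expression indicators, drop near-constant pairs, screen each
#' pair by univariate Cox regression on PFS at level `alpha`, select up to
#' `k_max` pairs by forward stepwise multivariate Cox (minimum AIC), and —
#' unless `cutoff_criterion = "none"` — set the classification cutoff at the
#' Youden-optimal threshold of the IPCW time-dependent ROC of the training
#' scores at `horizon_months`.
#'
#' @param expression Gene-by-sample matrix (any nonnegative within-sample
#'   comparable scale), or a `brgpi_cohort` (in which case `clinical` is
#'   taken from it).
#' @param clinical Data frame with at least `sample_id`, `pfs_months`,
#'   `event`, matched to the expression columns by id.
#' @param panel Candidate gene panel (default: all rows of the expression
#'   matrix, in their given order, which defines pair orientation).
#' @param alpha Univariate screening level (default 0.05, uncorrected).
#' @param min_frac Constancy filter threshold (default 0.2); pairs whose
#'   indicator mean falls outside `[min_frac, 1 - min_frac]` are dropped.
#' @param k_max Maximum number of pairs in the signature (default 4).
#' @param horizon_months ROC horizon for the cutoff, in months (default 12).
#' @param cutoff_criterion `"youden"` (default) or `"none"`.
#' @param ties Cox tie correction (`"efron"` default).
#' @return A `brgpi_signature` (also classed `brgpi`) with the screening
#'   table (`$screen`), training ROC (`$roc`), training scores
#'   (`$training_scores`) and joint fit (`$fit`) attached.
#' @seealso [predict.brgpi_signature()], [evaluate_cohort()]
#' @export
#' @examples
#' co <- generate_cohort(sim_config(n_samples = 120, n_genes = 15, seed = 3))
#' fit <- brgpi(co)
#' fit
brgpi <- function(expression, clinical = NULL, panel = NULL,
                  alpha = 0.05, min_frac = 0.2, k_max = 4,
                  horizon_months = 12,
                  cutoff_criterion = c("youden", "none"), ties = "efron") {
  cutoff_criterion <- match.arg(cutoff_criterion)
  if (inherits(expression, "brgpi_cohort")) {
    clinical <- expression$clinical
    expression <- expression$expression
  }
  if (is.null(clinical)) stop("clinical data are required", call. = FALSE)
  aligned <- align_cohort(expression, clinical)
  expression <- aligned$expression
  clinical <- aligned$clinical
  genes <- panel %||% rownames(expression)
  genes <- genes[genes %in% rownames(expression)]
  if (length(genes) < 2)
    stop("fewer than two panel genes present in the expression matrix",
         call. = FALSE)
  ind <- filter_pairs(encode_pairs(expression, build_pairs(genes)), min_frac)
  if (!nrow(ind$pairs))
    stop("no pairs survive the constancy filter", call. = FALSE)
  scr <- screen_pairs(ind, clinical$pfs_months, clinical$event, alpha = alpha,
                      ties = ties)
  if (!nrow(scr))
    stop("no pair passed the univariate screen at alpha = ", alpha,
         call. = FALSE)
  sig <- select_signature(scr, ind, clinical$pfs_months, clinical$event,
                          k_max = k_max, horizon_months = horizon_months,
                          ties = ties)
  scores <- score_brgpi(ind, sig)
  if (cutoff_criterion == "youden") {
    roc <- td_roc(scores, clinical$pfs_months, clinical$event, horizon_months)
    sig$cutoff <- roc$optimal_cutoff
    sig$roc <- roc
  }
  sig$screen <- scr
  sig$training_scores <- scores
  class(sig) <- c("brgpi", class(sig))
  sig
}
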