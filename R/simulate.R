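#' Simulation configuration for a synthetic immunotherapy cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The defaults emulate a bulk-expression immunotherapy cohort in which the
#' published four-pair signature is the planted truth: exponential PFS under
#' proportional hazards driven by the planted pair indicators, independent
#' uniform censoring calibrated to a target censored fraction, RECIST
#' response categories correlated with the latent risk, and a binary PD-L1
#' label.
#'
#' @param n_samples Number of patients.
#' @param n_genes Panel size; genes are taken from [immune_panel()] unless
#'   `gene_ids` is supplied. The planted-pair genes are always included.
#' @param planted_pairs Data frame with columns `gene_a`, `gene_b`, `beta`
#'   (log hazard ratio per indicator). Defaults to the published four pairs
#'   with their published coefficients.
#' @param baseline_hazard Baseline event rate per month (default 0.08/month,
#'   i.e. a baseline median PFS of about 8.7 months).
#' @param censor_rate Target fraction of censored subjects in `[0, 1)`.
#' @param horizon_months Evaluation horizon carried with the cohort (months).
#' @param platform Per-sample monotone distortion applied to the returned
#'   expression: `"linear"`, `"log"`, `"power"` or `"rank"`.
#' @param response_noise Scale of the logistic noise in the latent response
#'   model; 0 makes response a deterministic function of risk, larger values
#'   increase overlap between response groups.
#' @param pdl1_high_frac Probability that a sample is PD-L1 high.
#' @param pdl1_beta Optional log hazard ratio attached to PD-L1-low status
#'   (default 0: PD-L1 carries no prognostic effect, matching its observed
#'   non-prognostic behaviour in protein-level cohorts).
#' @param seed Integer seed; identical configs with identical seeds yield
#'   bit-identical cohorts.
#' @param gene_ids Optional explicit gene panel (overrides `n_genes`).
#'
#' @return An object of class `brgpi_sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_samples,
                       n_genes = 60L,
                       planted_pairs = NULL,
                       baseline_hazard = 0.08,
                       censor_rate = 0.2,
                       horizon_months = 12,
                       platform = c("linear", "log", "power", "rank"),
                       response_noise = 1,
                       pdl1_high_frac = 0.35,
                       pdl1_beta = 0,
                       seed = 1L,
                       gene_ids = NULL) {
  platform <- match.arg(platform)
  if (is.null(planted_pairs)) {
    sig <- published_signature()
    planted_pairs <- data.frame(gene_a = sig$pairs$gene_a,
                                gene_b = sig$pairs$gene_b,
                                beta = unname(sig$coefficients),
                                stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(planted_pairs),
            all(c("gene_a", "gene_b", "beta") %in% names(planted_pairs)))
  if (nrow(planted_pairs) && any(planted_pairs$gene_a == planted_pairs$gene_b))
    stop("planted pair genes must be distinct within each pair", call. = FALSE)
  if (!all(is.finite(planted_pairs$beta)))
    stop("planted coefficients must be finite", call. = FALSE)
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("n_samples must be a positive integer >= 2", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  if (horizon_months <= 0) stop("horizon_months must be positive", call. = FALSE)
  if (response_noise < 0) stop("response_noise must be >= 0", call. = FALSE)
  if (pdl1_high_frac < 0 || pdl1_high_frac > 1)
    stop("pdl1_high_frac must lie in [0, 1]", call. = FALSE)

  planted_genes <- unique(c(planted_pairs$gene_a, planted_pairs$gene_b))
  if (is.null(gene_ids)) {
    panel <- immune_panel()
    if (!all(planted_genes %in% panel))
      stop("planted pair genes must come from the gene panel: missing ",
           paste(setdiff(planted_genes, panel), collapse = ", "), call. = FALSE)
    if (n_genes > length(panel))
      stop("n_genes exceeds the bundled panel size (", length(panel), ")",
           call. = FALSE)
    if (n_genes < length(planted_genes))
      stop("panel too small to host the planted pairs: need at least ",
           length(planted_genes), " genes", call. = FALSE)
    extra <- setdiff(panel, planted_genes)
    gene_ids <- panel[panel %in% c(planted_genes,
                                   extra[seq_len(n_genes - length(planted_genes))])]
  } else {
    if (!all(planted_genes %in% gene_ids))
      stop("panel too small to host the planted pairs: missing ",
           paste(setdiff(planted_genes, gene_ids), collapse = ", "),
           call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = length(gene_ids),
                 gene_ids = gene_ids,
                 planted_pairs = planted_pairs,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 horizon_months = horizon_months,
                 platform = platform,
                 response_noise = response_noise,
                 pdl1_high_frac = pdl1_high_frac,
                 pdl1_beta = pdl1_beta,
                 seed = as.integer(seed)),
            class = "brgpi_sim_config")
}

# Solve the uniform-censoring upper bound C so that the expected censored
# fraction E[P(U < T)] with U ~ Unif(0, C] matches the target.
solve_censor_horizon <- function(rate, target) {
  f <- function(cc) mean((1 - exp(-rate * cc)) / (rate * cc)) - target
  hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  stats::uniroot(f, c(1e-9, hi), tol = 1e-9)$root
}

#' Generate a synthetic cohort with a planted gene-pair signature
#'
#' Draws a gene-by-sample expression matrix in which the configured gene
#' pairs drive PFS through a proportional-hazards model: the latent risk of
#' sample *i* is `r_i = sum_k beta_k s_k(i)` where `s_k(i)` is the
#' relative-expression indicator of planted pair *k* in the undistorted
#' expression, and event times are exponential with rate
#' `baseline_hazard * exp(r_i + pdl1_beta * [PD-L1 low])`. Censoring times
#' are uniform on `(0, C]` with `C` solved numerically so the expected
#' censored fraction equals `censor_rate`. RECIST response is drawn from a
#' latent variable `r_i + response_noise * logistic noise` cut at its
#' empirical 5% / 30% / 65% quantiles (CR / PR / SD / PD), so the
#' probability of progressive disease increases with risk. Non-planted genes
#' are independent log-normal noise; within each planted pair both genes
#' share a common mean so the indicator prevalence is near 1/2. Finally a
#' per-sample strictly monotone "platform" distortion is applied to the
#' expression, which never changes within-sample gene orderings.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `brgpi_cohort`: a list with `expression`
#'   (gene-by-sample matrix, distorted scale), `gene_ids`, `sample_ids`,
#'   `clinical` (data frame with `sample_id`, `pfs_months`, `event`,
#'   `response`, `pdl1`, `pathology`, `sex`), the `config`, and a `truth`
#'   list carrying the latent risk, planted-pair indicators and the
#'   undistorted expression for validation.
#' @export
#' @examples
#' co <- generate_cohort(sim_config(n_samples = 50, n_genes = 20, seed = 7))
#' dim(co$expression)
#' head(co$clinical)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "brgpi_sim_config"))
  set.seed(config$seed)
  genes <- config$gene_ids
  G <- length(genes)
  N <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(N))
  pp <- config$planted_pairs

  mu <- stats::rnorm(G, 0, 0.75)
  names(mu) <- genes
  if (nrow(pp)) {
    for (k in seq_len(nrow(pp))) {
      m <- mean(mu[c(pp$gene_a[k], pp$gene_b[k])])
      mu[pp$gene_a[k]] <- m
      mu[pp$gene_b[k]] <- m
    }
  }
  z <- matrix(stats::rnorm(G * N), G, N) + mu
  e0 <- exp(z)
  dimnames(e0) <- list(genes, sample_ids)

  if (nrow(pp)) {
    s <- (e0[pp$gene_a, , drop = FALSE] > e0[pp$gene_b, , drop = FALSE]) * 1L
    rownames(s) <- paste(pp$gene_a, pp$gene_b, sep = "|")
    r <- colSums(s * pp$beta)
  } else {
    s <- matrix(0L, 0, N)
    r <- rep(0, N)
  }

  pdl1 <- ifelse(stats::runif(N) < config$pdl1_high_frac, "high", "low")
  risk <- r + config$pdl1_beta * (pdl1 == "low")
  # center the linear predictor at its expectation (indicator prevalence 1/2)
  # so baseline_hazard describes the average patient; Cox coefficients are
  # invariant to this constant
  center <- sum(pp$beta) / 2 +
    config$pdl1_beta * (1 - config$pdl1_high_frac)
  rate <- config$baseline_hazard * exp(risk - center)
  t_event <- stats::rexp(N, rate)
  if (config$censor_rate > 0) {
    cmax <- solve_censor_horizon(rate, config$censor_rate)
    t_cens <- stats::runif(N, 0, cmax)
    pfs <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    cmax <- Inf
    pfs <- t_event
    event <- rep(1L, N)
  }

  u <- r + config$response_noise * stats::rlogis(N)
  th <- stats::quantile(u, c(0.05, 0.30, 0.65), names = FALSE)
  th <- th + (0:2) * 1e-9  # guard against tied quantiles when noise is 0
  response <- as.character(cut(u, c(-Inf, th, Inf),
                               labels = c("CR", "PR", "SD", "PD")))

  pathology <- ifelse(stats::runif(N) < 0.4, "squamous", "non_squamous")
  sex <- ifelse(stats::runif(N) < 0.6, "male", "female")

  expr <- apply_platform_distortion(e0, config$platform,
                                    seed = config$seed + 1L)

  clinical <- data.frame(sample_id = sample_ids,
                         pfs_months = pfs,
                         event = event,
                         response = response,
                         pdl1 = pdl1,
                         pathology = pathology,
                         sex = sex,
                         stringsAsFactors = FALSE)
  structure(list(expression = expr,
                 gene_ids = genes,
                 sample_ids = sample_ids,
                 clinical = clinical,
                 config = config,
                 truth = list(risk = r,
                              planted_indicators = s,
                              expression_undistorted = e0,
                              censor_horizon = cmax)),
            class = "brgpi_cohort")
}

#' @export
print.brgpi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d genes (platform: %s)\n",
              length(x$sample_ids), length(x$gene_ids), x$config$platform))
  cat(sprintf("  events: %d/%d, planted pairs: %d\n",
              sum(x$clinical$event), nrow(x$clinical),
              nrow(x$config$planted_pairs)))
  invisible(x)
}

#' Apply a per-sample monotone platform distortion
#'
#' Transforms every sample (column) of a nonnegative expression matrix by a
#' strictly increasing function, emulating scale differences between
#' measurement platforms (sequencing depth, TPM scaling, log compression,
#' ordinal IHC scoring). Because each transform is monotone within a sample,
#' the within-sample ordering of genes — and hence every gene-pair indicator
#' — is preserved exactly.
#'
#' @param expression Nonnegative gene-by-sample matrix.
#' @param platform One of `"linear"` (per-sample positive scale and
#'   nonnegative shift), `"log"` (`log1p`), `"power"` (per-sample exponent in
#'   `[0.5, 2]`), `"rank"` (within-sample ranks, average ties).
#' @param seed Optional seed for the sample-specific scale draws.
#' @param scale,shift Optional explicit per-sample (or scalar) parameters for
#'   the `"linear"` scale/shift or the `"power"` exponent; `scale = 1,
#'   shift = 0` returns the input unchanged.
#' @return Matrix of the same dimensions and dimnames.
#' @export
#' @examples
#' m <- matrix(c(1, 10, 100, 2, 5, 9), 3, 2)
#' d <- apply_platform_distortion(m, "log")
#' all(apply(m, 2, order) == apply(d, 2, order))
apply_platform_distortion <- function(expression,
                                      platform = c("linear", "log", "power", "rank"),
                                      seed = NULL, scale = NULL, shift = NULL) {
  platform <- match.arg(platform)
  expression <- as.matrix(expression)
  if (any(expression < 0)) stop("expression must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(expression)
  out <- switch(platform,
    linear = {
      a <- if (is.null(scale)) exp(stats::rnorm(N, 0, 0.5)) else rep_len(scale, N)
      b <- if (is.null(shift)) stats::runif(N, 0, 0.5) else rep_len(shift, N)
      if (any(a <= 0)) stop("linear scale must be positive", call. = FALSE)
      t(t(expression) * a + b)
    },
    log = log1p(expression),
    power = {
      g <- if (is.null(scale)) stats::runif(N, 0.5, 2) else rep_len(scale, N)
      if (any(g <= 0)) stop("power exponent must be positive", call. = FALSE)
      t(t(expression)^g)
    },
    rank = apply(expression, 2, rank, ties.method = "average"))
  dimnames(out) <- dimnames(expression)
  out
}

#' Write a cohort to plain-text files
#'
#' Writes the expression matrix as a TSV (first column `gene_id`, one column
#' per sample) and the clinical table as a CSV with header
#' `sample_id,pfs_months,event,response,pdl1,pathology,sex`.
#'
#' @param cohort A `brgpi_cohort` (or any list with `expression` and
#'   `clinical` components).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  cp <- file.path(dir, "clinical.csv")
  write_expression(cohort$expression, ep)
  write_clinical(cohort$clinical, cp)
  invisible(c(expression = ep, clinical = cp))
}
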