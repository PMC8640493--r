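# Independent oracles, kept free of the package's model-fitting code paths.

# Hand-coded Cox partial log-likelihood with Efron tie correction,
# scalar covariate.
efron_loglik <- function(beta, time, event, x) {
  eta <- x * beta
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sw_R <- sum(w[R])
    sw_D <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(sw_R - (seq_len(d) - 1) / d * sw_D))
  }
  ll
}

# Brute-force maximizer of the Efron partial likelihood over [-10, 10]:
# coarse grid refined by golden-section search.
brute_cox_beta <- function(time, event, x) {
  grid <- seq(-10, 10, by = 0.05)
  ll <- vapply(grid, efron_loglik, 0, time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(efron_loglik, c(max(-10, b0 - 0.1), min(10, b0 + 0.1)),
                  time = time, event = event, x = x,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# Exhaustive pair-counting empirical AUC (ties count 1/2).
pair_count_auc <- function(scores, is_case) {
  sc1 <- scores[is_case]
  sc0 <- scores[!is_case]
  tot <- 0
  for (a in sc1) tot <- tot + sum(a > sc0) + 0.5 * sum(a == sc0)
  tot / (length(sc1) * length(sc0))
}

# Monte-Carlo permutation p-value for the log-rank statistic.
perm_logrank_p <- function(group, time, event, B, seed = 1) {
  obs <- logrank_test(group, time, event)$statistic
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    g <- sample(group)
    if (logrank_test(g, time, event)$statistic >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / B
}

# Small survival fixtures with n <= 8 and a finite partial-likelihood
# maximizer (covariate groups interleaved in time so the likelihood is not
# monotone); two fixtures carry tied event times to exercise the Efron
# correction.
surv_fixtures <- function() {
  list(
    list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
         x = c(1, 0, 1, 0)),
    list(time = c(2, 1, 4, 3, 6, 5), event = c(1, 1, 1, 1, 1, 1),
         x = c(1, 0, 0, 1, 1, 0)),
    list(time = c(1, 1, 2, 3, 3, 4, 5, 5), event = rep(1, 8),
         x = c(1, 0, 1, 0, 1, 0, 0, 1)),
    list(time = c(2, 2, 2, 5, 5, 7, 8, 9), event = c(1, 1, 0, 1, 1, 1, 0, 1),
         x = c(1, 0, 1, 0, 1, 0, 1, 0)),
    list(time = c(3, 1, 4, 1, 5, 9, 2, 6), event = c(1, 0, 1, 1, 0, 1, 1, 1),
         x = c(0, 1, 1, 0, 1, 0, 1, 0)))
}

small_cohort <- function(seed = 1, n = 60, genes = 15, ...) {
  generate_cohort(sim_config(n_samples = n, n_genes = genes, seed = seed, ...))
}

null_pairs <- function(beta = 0) {
  sig <- published_signature()
  data.frame(gene_a = sig$pairs$gene_a, gene_b = sig$pairs$gene_b,
             beta = beta, stringsAsFactors = FALSE)
}
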