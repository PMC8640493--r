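make_indicator_obj <- function(values, sample_ids = colnames(values)) {
  parts <- strsplit(rownames(values), "|", fixed = TRUE)
  pairs <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                      gene_b = vapply(parts, `[`, "", 2),
                      pair_id = rownames(values), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, sample_ids = sample_ids, values = values),
            class = "brgpi_pairs")
}

test_that("index scores are exact weighted indicator sums", {
  sig <- published_signature()
  v <- cbind(s1 = c(1L, 1L, 1L, 1L),
             s2 = c(0L, 0L, 0L, 0L),
             s3 = c(1L, 0L, 1L, 0L))
  rownames(v) <- sig$pairs$pair_id
  ind <- make_indicator_obj(v)
  sc <- score_brgpi(ind, sig)
  expect_equal(unname(sc["s1"]), 1.521 + 1.257 - 1.495 + 1.812)
  expect_equal(unname(sc["s2"]), 0)
  expect_equal(unname(sc["s3"]), 1.521 - 1.495)
  # linearity: flipping one indicator moves the score by its coefficient
  v2 <- v
  v2["CDK1|CXCL9", "s3"] <- 1L
  sc2 <- score_brgpi(make_indicator_obj(v2), sig)
  expect_equal(unname(sc2["s3"] - sc["s3"]), 1.257)
  # missing pair errors by name
  expect_error(score_brgpi(make_indicator_obj(v[-2, , drop = FALSE]), sig),
               "CDK1|CXCL9", fixed = TRUE)
})

test_that("classification is strict-greater with boundary to low", {
  sc <- c(a = 3.095, b = 0.026, c = 0.317, d = 0.3171)
  cls <- classify(sc, 0.317)
  expect_identical(as.character(cls), c("high", "low", "low", "high"))
  expect_true(all(classify(sc, -10) == "high"))
  expect_error(classify(sc, Inf), "finite")
  # monotone: raising scores never moves a sample from high to low
  raised <- classify(sc + 1, 0.317)
  expect_true(all(!(cls == "high" & raised == "low")))
  expect_identical(as.character(classify(sc + 10, 0.317)), rep("high", 4))
})

test_that("cohort evaluation assembles ROC, survival and response statistics", {
  co <- small_cohort(seed = 51, n = 250, genes = 12, censor_rate = 0.2)
  rep <- evaluate_cohort(co, published_signature())
  expect_gt(rep$auc, 0.7)
  expect_lt(rep$logrank$p, 0.001)
  expect_equal(sum(rep$group_sizes), 250)
  expect_true(all(c("index_high", "sex_male", "pathology_squamous",
                    "pdl1_high") %in% rep$cox_univariate$term))
  expect_true("index_high" %in% rep$cox_multivariate$term)
  expect_lt(rep$response_tests$kruskal_crpr_sd_pd$p, 0.05)
  expect_true(all(c("response_vs_nonresponse", "pd_vs_nonpd") %in%
                    names(rep$response_tests)))
  # high-risk group progresses earlier
  expect_lt(rep$median_pfs[["high"]], rep$median_pfs[["low"]])
})

test_that("degenerate groupings are skipped with warnings, not errors", {
  co <- small_cohort(seed = 52, n = 60, genes = 12, censor_rate = 0.2)
  co$clinical$response <- "PD"
  sig <- published_signature()
  expect_warning(rep <- evaluate_cohort(co, sig), "degenerate")
  expect_null(rep$response_tests$kruskal_crpr_sd_pd)
  # an all-low classification skips the log-rank
  sig_hi <- sig
  sig_hi$cutoff <- 100
  co2 <- small_cohort(seed = 53, n = 40, genes = 12)
  expect_warning(rep2 <- evaluate_cohort(co2, sig_hi), "empty")
  expect_null(rep2$logrank)
  sig_na <- sig
  sig_na$cutoff <- NA_real_
  expect_error(evaluate_cohort(co2, sig_na), "cutoff")
})

test_that("stratified survival comparisons run within pathology and PD-L1 strata", {
  co <- small_cohort(seed = 54, n = 400, genes = 12, censor_rate = 0.2)
  st <- stratified_km(co, published_signature(), "pathology")
  expect_setequal(st$stratum, c("squamous", "non_squamous"))
  expect_true(all(st$testable))
  expect_true(all(st$median_low > st$median_high))
  expect_true(all(st$p < 0.01))
  st2 <- stratified_km(co, published_signature(), "pdl1")
  expect_true(all(st2$testable))
})

test_that("strata with a single index group are reported as non-testable", {
  co <- small_cohort(seed = 55, n = 40, genes = 12)
  sig <- published_signature()
  sig$cutoff <- -100  # everyone high
  st <- suppressWarnings(stratified_km(co, sig, "pathology"))
  expect_true(all(!st$testable))
  expect_true(all(is.na(st$p)))
})

test_that("index x PD-L1 grouping assigns the three groups by favorability", {
  co <- small_cohort(seed = 56, n = 300, genes = 12, censor_rate = 0.2,
                     pdl1_beta = 0.7)
  sig <- published_signature()
  pc <- pdl1_combined_groups(co, sig)
  grp <- classify(predict(sig, co), sig$cutoff)
  pdl1 <- co$clinical$pdl1
  expect_identical(as.character(pc$labels[grp == "low" & pdl1 == "high"][1]),
                   "both_favorable")
  expect_identical(as.character(pc$labels[grp == "high" & pdl1 == "low"][1]),
                   "neither_favorable")
  expect_identical(as.character(pc$labels[grp == "low" & pdl1 == "low"][1]),
                   "one_favorable")
  # both effects planted: favorability orders median PFS
  m <- pc$median_pfs
  expect_gte(m[["both_favorable"]], m[["one_favorable"]])
  expect_gte(m[["one_favorable"]], m[["neither_favorable"]])
  expect_lt(pc$logrank$p, 0.01)
})

test_that("samples with missing PD-L1 are excluded and counted", {
  co <- small_cohort(seed = 57, n = 80, genes = 12)
  co$clinical$pdl1[1:5] <- NA
  expect_warning(pc <- pdl1_combined_groups(co, published_signature()),
                 "excluded")
  expect_equal(pc$n_excluded, 5)
  expect_equal(sum(pc$n), 75)
})

test_that("shuffled index labels give uniform stratum p-values", {
  pvals <- vapply(1:100, function(i) {
    set.seed(7000 + i)
    n <- 80
    tm <- rexp(n, 0.1)
    g <- sample(c("low", "high"), n, replace = TRUE)
    logrank_test(g, tm, rep(1, n))$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
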