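test_that("the frozen published signature carries the printed values", {
  sig <- published_signature()
  expect_identical(unname(sig$coefficients), c(1.521, 1.257, -1.495, 1.812))
  expect_identical(sig$pairs$pair_id,
                   c("CCL2|VEGFA", "CDK1|CXCL9", "HLA-DOB|LCK", "IL12A|TBX21"))
  expect_identical(sig$cutoff, 0.317)
  expect_identical(sig$horizon_months, 12)
})

test_that("screening returns every non-constant pair at alpha = 1", {
  co <- small_cohort(seed = 31, n = 80, genes = 10)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  nonconst <- sum(rowMeans(ind$values) > 0 & rowMeans(ind$values) < 1)
  scr <- suppressWarnings(
    screen_pairs(ind, co$clinical$pfs_months, co$clinical$event, alpha = 1))
  expect_equal(nrow(scr), nonconst)
  expect_true(all(diff(scr$p) >= 0))
})

test_that("constant indicator rows are skipped with a warning, not errors", {
  co <- small_cohort(seed = 32, n = 40, genes = 8)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  ind$values[1, ] <- 1L  # force a constant row
  expect_warning(
    scr <- screen_pairs(ind, co$clinical$pfs_months, co$clinical$event,
                        alpha = 1),
    "constant")
  expect_equal(attr(scr, "n_skipped"), 1)
  expect_false(ind$pairs$pair_id[1] %in% scr$pair_id)
})

test_that("screening retains planted pairs and its betas match univariate fits", {
  co <- small_cohort(seed = 33, n = 300, genes = 15, censor_rate = 0.2)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  scr <- screen_pairs(ind, co$clinical$pfs_months, co$clinical$event,
                      alpha = 0.05)
  planted <- rownames(co$truth$planted_indicators)
  expect_true(all(planted %in% scr$pair_id))
  k <- scr$pair_id[1]
  f <- fit_cox(co$clinical$pfs_months, co$clinical$event, ind$values[k, ])
  expect_equal(scr$beta[1], unname(f$coefficients), tolerance = 1e-10)
})

test_that("stepwise selection over exactly the planted candidates recovers them", {
  co <- small_cohort(seed = 34, n = 1000, genes = 15, censor_rate = 0.2)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  planted <- co$config$planted_pairs
  cand_ids <- paste(planted$gene_a, planted$gene_b, sep = "|")
  cand <- data.frame(pair_id = cand_ids, gene_a = planted$gene_a,
                     gene_b = planted$gene_b, p = seq(0.001, 0.004, 0.001))
  sig <- select_signature(cand, ind, co$clinical$pfs_months,
                          co$clinical$event, k_max = 4)
  expect_setequal(sig$pairs$pair_id, cand_ids)
  rel <- abs(sig$coefficients[cand_ids] - planted$beta) / abs(planted$beta)
  expect_true(all(rel < 0.25))
})

test_that("k_max = 2 reproduces the AIC-best forward path among strong candidates", {
  co <- small_cohort(seed = 35, n = 400, genes = 15, censor_rate = 0.2)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  planted <- co$config$planted_pairs
  cand_ids <- paste(planted$gene_a, planted$gene_b, sep = "|")
  cand <- data.frame(pair_id = cand_ids, gene_a = planted$gene_a,
                     gene_b = planted$gene_b, p = seq(0.001, 0.004, 0.001))
  sig <- select_signature(cand, ind, co$clinical$pfs_months,
                          co$clinical$event, k_max = 2)
  expect_equal(nrow(sig$pairs), 2)
  # forward path: best single-pair AIC, then best partner given that pair
  tm <- co$clinical$pfs_months; ev <- co$clinical$event
  aic1 <- vapply(cand_ids, function(k)
    -2 * fit_cox(tm, ev, ind$values[k, ])$log_partial_likelihood + 2, 0)
  first <- cand_ids[which.min(aic1)]
  aic2 <- vapply(setdiff(cand_ids, first), function(k)
    -2 * fit_cox(tm, ev, t(ind$values[c(first, k), ]))$log_partial_likelihood + 4, 0)
  second <- names(aic2)[which.min(aic2)]
  expect_setequal(sig$pairs$pair_id, c(first, second))
})

test_that("a single candidate yields a size-1 signature with its univariate beta", {
  co <- small_cohort(seed = 36, n = 200, genes = 10, censor_rate = 0.2)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  planted <- co$config$planted_pairs[1, ]
  k <- paste(planted$gene_a, planted$gene_b, sep = "|")
  cand <- data.frame(pair_id = k, gene_a = planted$gene_a,
                     gene_b = planted$gene_b, p = 0.001)
  sig <- select_signature(cand, ind, co$clinical$pfs_months, co$clinical$event)
  expect_equal(nrow(sig$pairs), 1)
  f <- fit_cox(co$clinical$pfs_months, co$clinical$event, ind$values[k, ])
  expect_equal(unname(sig$coefficients), unname(f$coefficients),
               tolerance = 1e-10)
})

test_that("selection is deterministic and orientation flips only change signs", {
  co <- small_cohort(seed = 37, n = 150, genes = 10, censor_rate = 0.2)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  tm <- co$clinical$pfs_months; ev <- co$clinical$event
  scr1 <- screen_pairs(ind, tm, ev, alpha = 0.2)
  scr2 <- screen_pairs(ind, tm, ev, alpha = 0.2)
  expect_identical(scr1, scr2)
  # flip one screened pair's orientation: same screen membership, negated beta
  k <- scr1$pair_id[1]
  ind2 <- ind
  ind2$values[k, ] <- 1L - ind2$values[k, ]
  scr3 <- screen_pairs(ind2, tm, ev, alpha = 0.2)
  expect_setequal(scr3$pair_id, scr1$pair_id)
  expect_equal(scr3$beta[scr3$pair_id == k], -scr1$beta[scr1$pair_id == k],
               tolerance = 1e-8)
})

test_that("signature JSON round trip is lossless", {
  sig <- published_signature()
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$coefficients, sig$coefficients)
  expect_identical(back$cutoff, sig$cutoff)
  expect_identical(back$pairs, sig$pairs)
  expect_identical(back$horizon_months, sig$horizon_months)
  # unset cutoff survives the round trip too
  sig2 <- new_brgpi_signature(sig$pairs, unname(sig$coefficients))
  path2 <- withr::local_tempfile(fileext = ".json")
  write_signature(sig2, path2)
  expect_true(is.na(read_signature(path2)$cutoff))
})

test_that("the full fitting front door trains, cuts and predicts", {
  co <- small_cohort(seed = 38, n = 200, genes = 12, censor_rate = 0.2)
  fit <- brgpi(co)
  expect_s3_class(fit, "brgpi_signature")
  expect_true(is.finite(fit$cutoff))
  sc <- predict(fit, co)
  expect_length(sc, 200)
  cls <- predict(fit, co, type = "class")
  expect_s3_class(cls, "factor")
  expect_identical(levels(cls), c("low", "high"))
})
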