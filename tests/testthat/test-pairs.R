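test_that("panel intersection keeps canonical order and reports misses", {
  expect_equal(intersect_panel(list(c("A", "B", "C"), c("B", "C", "D")),
                               c("A", "B", "C")),
               c("B", "C"))
  expect_equal(intersect_panel(list(c("A", "B", "C")), c("A", "B", "C")),
               c("A", "B", "C"))
  expect_error(intersect_panel(list(c("X", "Y")), c("A", "B")),
               "no panel gene")
  expect_error(intersect_panel(list(), c("A")), "at least one")
})

test_that("pair enumeration has the right count and orientation", {
  expect_equal(nrow(build_pairs(c("A", "B", "C"))), 3)
  expect_equal(nrow(build_pairs(paste0("g", 1:222))), 24531)
  p <- build_pairs(c("Z_FIRST", "A_SECOND"))
  expect_equal(p$gene_a, "Z_FIRST")  # orientation follows panel order
  expect_equal(p$pair_id, "Z_FIRST|A_SECOND")
  expect_error(build_pairs("A"), "two genes")
})

test_that("indicator encoding follows the strict-greater rule with ties to 0", {
  m <- matrix(c(7.1, 2.3, 3.0,
                2.3, 7.1, 3.0,
                3.0, 3.0, 1.0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  pr <- build_pairs(c("a", "b"))
  ind <- encode_pairs(m, pr)
  expect_identical(as.integer(ind$values["a|b", ]), c(1L, 0L, 0L))
  expect_error(encode_pairs(m, build_pairs(c("a", "zzz"))), "zzz")
})

test_that("encoding is invariant to strictly increasing per-sample transforms", {
  co <- small_cohort(seed = 4, n = 25, genes = 10)
  e0 <- co$truth$expression_undistorted
  pr <- build_pairs(rownames(e0))
  ref <- encode_pairs(e0, pr)$values
  for (pf in c("linear", "log", "power", "rank")) {
    d <- apply_platform_distortion(e0, pf, seed = 17)
    expect_identical(encode_pairs(d, pr)$values, ref)
  }
  # adding a per-sample constant only shifts levels, not sign patterns
  shifted <- sweep(e0, 2, runif(ncol(e0), 0, 5), "+")
  expect_identical(encode_pairs(shifted, pr)$values, ref)
})

test_that("orientation flip maps indicators to their complement on tie-free data", {
  co <- small_cohort(seed = 6, n = 20, genes = 8)
  e0 <- co$truth$expression_undistorted
  fwd <- encode_pairs(e0, data.frame(gene_a = "CCL2", gene_b = "VEGFA",
                                     pair_id = "CCL2|VEGFA"))
  rev <- encode_pairs(e0, data.frame(gene_a = "VEGFA", gene_b = "CCL2",
                                     pair_id = "VEGFA|CCL2"))
  expect_identical(as.integer(rev$values), 1L - as.integer(fwd$values))
})

test_that("constancy filter keeps mid-prevalence pairs and is idempotent", {
  v <- rbind(rep(1L, 10),                 # constant 1
             rep(0L, 10),                 # constant 0
             c(rep(1L, 5), rep(0L, 5)),   # mean 0.5
             c(1L, rep(0L, 9)),           # mean 0.1
             c(rep(1L, 3), rep(0L, 7)),   # mean 0.3
             c(rep(1L, 8), rep(0L, 2)),   # mean 0.8
             c(rep(1L, 9), 0L),           # mean 0.9
             c(rep(1L, 2), rep(0L, 8)),   # mean 0.2
             c(rep(1L, 4), rep(0L, 6)),   # mean 0.4
             c(rep(1L, 6), rep(0L, 4)))   # mean 0.6
  pairs <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10),
                      pair_id = paste0("p", 1:10))
  rownames(v) <- pairs$pair_id
  ind <- structure(list(pairs = pairs, sample_ids = paste0("s", 1:10),
                        values = v), class = "brgpi_pairs")
  f <- filter_pairs(ind, 0.25)
  expect_equal(nrow(f$values), 4)  # means 0.5, 0.3, 0.4, 0.6
  expect_identical(filter_pairs(f, 0.25)$values, f$values)
  expect_equal(nrow(filter_pairs(ind, 0.2)$values), 6)
  expect_error(filter_pairs(ind, 0.6), "min_frac")
  expect_error(filter_pairs(ind, 0), "min_frac")
})

test_that("indicator TSV round trip is lossless", {
  co <- small_cohort(seed = 2, n = 12, genes = 8)
  ind <- encode_pairs(co$expression, build_pairs(co$gene_ids))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indicators(ind, path)
  back <- read_indicators(path)
  expect_identical(back$values, ind$values)
  expect_equal(back$pairs$gene_a, ind$pairs$gene_a)
})
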