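make_block <- function(v, windows = NULL) {
  if (is.null(colnames(v))) colnames(v) <- sprintf("S%02d", seq_len(ncol(v)))
  if (is.null(rownames(v))) rownames(v) <- sprintf("f%02d", seq_len(nrow(v)))
  omics_block(v, "test", sample_windows = windows)
}

test_that("log2 transform handles pseudocounts, NA, and negatives", {
  b <- make_block(matrix(c(4, 0, 7, NA), 1, 4))
  expect_equal(unname(log2_transform(b, 0)$values[1, 1]), 2)
  expect_equal(unname(log2_transform(b, 1)$values[1, 2]), 0)
  expect_equal(unname(log2_transform(b, 1)$values[1, 3]), 3)  # log2(8)
  expect_true(is.na(log2_transform(b, 1)$values[1, 4]))

  bad <- make_block(matrix(c(1, -2), 1, 2))
  expect_error(log2_transform(bad), "f01.*S02")
})

test_that("prevalence filter uses a strict threshold", {
  v <- matrix(1, 3, 18)
  v[1, 7:18] <- NA   # present 6/18 -> dropped at 1/3 (not strictly above)
  v[2, 8:18] <- NA   # present 7/18 -> kept
  b <- make_block(v)
  expect_message(f <- prevalence_filter(b, 1 / 3), "dropping 1")
  expect_setequal(feature_ids(f), c("f02", "f03"))

  v2 <- matrix(1, 2, 4); v2[1, 1] <- NA
  expect_equal(feature_ids(prevalence_filter(make_block(v2), 1)), "f02")
})

test_that("KNN imputation fills holes from nearest features", {
  v <- matrix(rnorm(20), 4, 5)
  b <- make_block(v)
  expect_identical(knn_impute(b, 2)$values, b$values)  # no missing: identity

  # identical twin features: the hole is filled with the twin's value (k=1)
  v2 <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), c(9, 1, 4, 2, 7))
  v2[1, 3] <- NA
  b2 <- make_block(v2)
  expect_equal(unname(knn_impute(b2, 1)$values[1, 3]), 3)

  expect_error(knn_impute(b2, 5), "neighbours")
  v3 <- v2; v3[2, ] <- NA
  expect_error(knn_impute(make_block(v3), 1), "no observed values")
})

test_that("residualization removes covariates, preserves means, idempotent", {
  set.seed(11)
  n <- 12
  cov <- data.frame(sample_id = sprintf("S%02d", 1:n),
                    fiber = rep(c(0, 1), each = n / 2))
  v <- matrix(rnorm(3 * n, mean = 5), 3, n)
  b <- make_block(v)

  zero <- cov; zero$fiber <- 0
  expect_equal(residualize(b, zero)$values, b$values)  # intercept-only

  # feature exactly equal to the covariate: residuals collapse to the mean
  v2 <- v; v2[1, ] <- cov$fiber
  r <- residualize(make_block(v2), cov)
  expect_equal(unname(r$values[1, ]), rep(mean(cov$fiber), n))

  # orthogonal feature unchanged
  orth <- rep(c(1, -1), n / 2) * rep(c(1, 1, -1, -1), n / 4)
  orth <- orth - mean(orth)
  stopifnot(abs(sum(orth * (cov$fiber - mean(cov$fiber)))) < 1e-12)
  v3 <- v; v3[2, ] <- orth + 3
  r3 <- residualize(make_block(v3), cov)
  expect_equal(unname(r3$values[2, ]), orth + 3, tolerance = 1e-12)

  once <- residualize(b, cov)
  twice <- residualize(once, cov)
  expect_equal(twice$values, once$values, tolerance = 1e-10)
})

test_that("fiber covariates flag the dosing periods", {
  sw <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    start_date = c("2016-01-10", "2016-01-30", "2016-02-25", "2016-03-20"),
    end_date = c("2016-01-12", "2016-02-01", "2016-02-26", "2016-03-22"))
  fc <- fiber_covariates(sw)
  expect_equal(fc$arabinoxylan, c(0L, 1L, 0L, 0L))
  expect_equal(fc$guar_gum, c(0L, 0L, 1L, 0L))
})

test_that("block alignment pairs overlapping windows one-to-one", {
  win <- function(ids, starts, ends) {
    data.frame(sample_id = ids, start_date = as.Date(starts),
               end_date = as.Date(ends), stringsAsFactors = FALSE)
  }
  blk <- function(w) {
    v <- matrix(seq_len(nrow(w)), 1, nrow(w),
                dimnames = list("f", w$sample_id))
    omics_block(v, "x", w)
  }
  wa <- win(c("A1", "A2"), c("2016-01-01", "2016-01-05"),
            c("2016-01-02", "2016-01-06"))
  al <- align_blocks(blk(wa), blk(wa), tolerance_days = 0)
  expect_equal(al$sample_a, al$sample_b)  # identical windows: identity

  wb <- win("B1", "2016-02-01", "2016-02-02")
  expect_error(align_blocks(blk(wa), blk(wb), tolerance_days = 0),
               "tolerance")

  # A covers Jan 1-3; B offers Jan 2-2 and Jan 5-5: the overlapping B wins
  wa2 <- win("A1", "2016-01-01", "2016-01-03")
  wb2 <- win(c("B1", "B2"), c("2016-01-02", "2016-01-05"),
             c("2016-01-02", "2016-01-05"))
  al2 <- align_blocks(blk(wa2), blk(wb2), tolerance_days = 0)
  expect_equal(al2$sample_b, "B1")
  expect_equal(al2$overlap_days, 1L)

  # symmetry when no tie-breaks fire
  wa3 <- win(c("A1", "A2", "A3"),
             c("2016-01-01", "2016-01-04", "2016-01-09"),
             c("2016-01-03", "2016-01-06", "2016-01-10"))
  wb3 <- win(c("B1", "B2", "B3"),
             c("2016-01-02", "2016-01-06", "2016-01-08"),
             c("2016-01-04", "2016-01-07", "2016-01-09"))
  ab <- align_blocks(blk(wa3), blk(wb3), tolerance_days = 0)
  ba <- align_blocks(blk(wb3), blk(wa3), tolerance_days = 0)
  expect_setequal(paste(ab$sample_a, ab$sample_b),
                  paste(ba$sample_b, ba$sample_a))
  expect_false(any(duplicated(ab$sample_a)))
  expect_false(any(duplicated(ab$sample_b)))
})

test_that("spearman correlations are invariant to the log2 transform", {
  set.seed(3)
  v <- matrix(exp(rnorm(40)), 4, 10)
  b <- make_block(v)
  bl <- log2_transform(b, 1)
  for (i in 1:3) {
    r_raw <- spearman_rho(b$values[i, ], b$values[i + 1, ])$rho
    r_log <- spearman_rho(bl$values[i, ], bl$values[i + 1, ])$rho
    expect_equal(r_raw, r_log, tolerance = 1e-12)
  }
})
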