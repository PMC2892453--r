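test_that("flooring replaces sub-floor values and nothing else", {
  m <- make_em(cbind(c(-2, 0.5, 3), c(5, 6, -1)))
  f <- floor_values(m)
  expect_equal(unname(f$values[, 1]), c(1, 1, 3))
  expect_equal(unname(f$values[, 2]), c(5, 6, 1))
  expect_identical(f$flags, m$flags)

  untouched <- make_em(cbind(c(5, 6), c(7, 8)))
  expect_equal(floor_values(untouched)$values, untouched$values)

  all_neg <- make_em(matrix(c(-3, -1, -2, -9), 2))
  expect_true(all(floor_values(all_neg)$values == 1))

  logm <- make_em(matrix(1:4, 2), scale = "log2")
  expect_error(floor_values(logm), class = "flumir_state_error")
})

test_that("quantile normalization maps columns onto the rank-mean reference", {
  same <- make_em(cbind(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(quantile_normalize(same)$values, same$values)

  m <- make_em(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))
  expect_identical(qn$scale, "normalized-linear")

  # tie rule: tied cells share the mean of the reference values at their
  # tied ranks; reference here is (2, 3, 4.5)
  tied <- make_em(cbind(c(1, 1, 2), c(3, 5, 7)))
  qt <- quantile_normalize(tied)
  expect_equal(unname(qt$values[, 1]), c(2.5, 2.5, 4.5))
  expect_equal(unname(qt$values[, 2]), c(2, 3, 4.5))

  expect_warning(quantile_normalize(make_em(matrix(1:3))), "2 samples")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(42)
  v <- matrix(stats::rlnorm(300, 5, 2), 60, 5)
  qn <- quantile_normalize(make_em(v))
  ref <- limma::normalizeQuantiles(v, ties = TRUE)
  expect_equal(unname(qn$values), unname(ref), tolerance = 1e-12)
})

test_that("column distributions are exactly equal and the operation idempotent", {
  set.seed(7)
  for (i in 1:20) {
    v <- matrix(stats::rlnorm(40 * 4, 3, 2), 40, 4)
    v[v < 1] <- 1  # floored values introduce ties
    m <- make_em(v)
    qn <- quantile_normalize(m, ties = "first")
    sorted <- unname(apply(qn$values, 2, sort))
    expect_equal(sorted, sorted[, c(2:4, 1)], tolerance = 0)
    expect_equal(quantile_normalize(qn, ties = "first")$values, qn$values,
                 tolerance = 0)

    # the tie-averaging dialect holds the same properties on tie-free input
    v2 <- matrix(stats::rlnorm(40 * 4, 3, 2), 40, 4)
    qn2 <- quantile_normalize(make_em(v2))
    sorted2 <- unname(apply(qn2$values, 2, sort))
    expect_equal(sorted2, sorted2[, c(2:4, 1)], tolerance = 0)
    expect_equal(quantile_normalize(qn2)$values, qn2$values, tolerance = 0)
  }
})

test_that("log2 transform is exact, guarded and invertible", {
  m <- make_em(matrix(c(8, 1, 2, 16), 2), scale = "normalized-linear")
  lg <- log2_transform(m)
  expect_equal(unname(lg$values), matrix(c(3, 0, 1, 4), 2))
  expect_identical(lg$scale, "log2")
  expect_equal(2^lg$values, m$values)

  with_zero <- make_em(matrix(c(0, 1, 2, 3), 2))
  expect_error(log2_transform(with_zero), class = "flumir_state_error")
})

test_that("presence filtering keeps features present in >= min_present samples", {
  flags <- cbind(c(FALSE, TRUE, TRUE), c(FALSE, FALSE, TRUE))
  m <- make_em(matrix(1:6, 3), flags = flags)
  kept <- presence_filter(m)
  expect_identical(rownames(kept$values), c("f02", "f03"))

  all_present <- make_em(matrix(1:6, 3))
  expect_identical(presence_filter(all_present)$values, all_present$values)

  expect_identical(rownames(presence_filter(m, min_present = 2)$values), "f03")
  expect_error(presence_filter(m, min_present = 3),
               class = "flumir_parameter_error")
})

test_that("the preprocessing chain is order-sensitive and enforced in order", {
  set.seed(11)
  v <- matrix(stats::rlnorm(60, 2, 2), 20, 3)
  v[sample(length(v), 5)] <- -v[sample(length(v), 5)]
  m <- make_em(v)
  canonical <- log2_transform(quantile_normalize(floor_values(m)))
  permuted <- log2_transform(floor_values(quantile_normalize(m)))
  expect_false(isTRUE(all.equal(canonical$values, permuted$values)))

  # log2 before flooring is refused outright
  expect_error(log2_transform(m), class = "flumir_state_error")
  full <- preprocess_expression(m)
  expect_identical(full$scale, "log2")
  expect_equal(full$values, canonical$values)
})
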