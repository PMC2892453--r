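test_that("group summaries are geometric means of linear intensities", {
  expect_equal(group_summary(c(2, 8)), 4)
  expect_equal(group_summary(3.7), 3.7)
  set.seed(1)
  x <- stats::rlnorm(50, 2, 1)
  expect_equal(group_summary(x), exp(mean(log(x))), tolerance = 1e-12)
  expect_error(group_summary(numeric(0)), class = "flumir_parameter_error")
  expect_error(group_summary(c(1, -1)), class = "flumir_parameter_error")
})

test_that("fold changes reproduce published group-mean ratios and flip with order", {
  fc <- fold_change(8.13, 2.23)
  expect_equal(round(fc$fold_change, 2), 3.65)
  expect_identical(fc$direction, "up")

  fc2 <- fold_change(1.14, 2.51)
  expect_lte(abs(round(fc2$fold_change, 2) - 2.21), 0.01)
  expect_identical(fc2$direction, "down")

  expect_equal(fold_change(5, 5), data.frame(fold_change = 1, direction = "up",
                                             stringsAsFactors = FALSE))

  set.seed(2)
  a <- stats::rlnorm(20); b <- stats::rlnorm(20)
  fwd <- fold_change(a, b); rev <- fold_change(b, a)
  expect_equal(fwd$fold_change, rev$fold_change)
  expect_true(all((fwd$direction == rev$direction) == (a == b)))
})

test_that("Welch p-values match stats::t.test and honour the degenerate conventions", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(welch_test(c(2, 2, 2), c(2, 2, 2)), 1)

  a <- c(1, 2, 3); b <- c(2, 4, 6)
  ref <- stats::t.test(a, b, var.equal = FALSE)$p.value
  expect_equal(welch_test(a, b), ref, tolerance = 1e-12)
  expect_equal(welch_test(b, a), welch_test(a, b))

  set.seed(3)
  for (i in 1:50) {
    x <- stats::rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    y <- stats::rnorm(sample(3:10, 1), mean = runif(1, -2, 2))
    expect_equal(welch_test(x, y),
                 stats::t.test(x, y, var.equal = FALSE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(welch_test(1, c(1, 2)), class = "flumir_parameter_error")
  # zero-noise limit: constant unequal groups give a vanishing positive p
  p0 <- welch_test(c(2, 2, 2), c(5, 5, 5))
  expect_gt(p0, 0)
  expect_lt(p0, 1e-300)
})

test_that("BH adjustment matches the longhand step-up and dominates its input", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_manual(p), tolerance = 1e-14)
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "flumir_parameter_error")
})

test_that("group comparison recovers a planted marker exactly in the noise-free limit", {
  markers <- data.frame(feature_id = "the-marker", fold = 3, direction = "up")
  d <- noiseless_design(n_features = 100, planted_markers = markers,
                        include_post = FALSE, seed = 10)
  g <- generate_cohort(d)
  pm <- log2_transform(floor_values(g$matrix))
  res <- compare_groups(pm, g$samples, criteria = selection_criteria(max_p = 1))
  expect_identical(selected_markers(res)$feature_id, "the-marker")

  vac <- compare_groups(pm, g$samples,
                        criteria = selection_criteria(min_fold = 1, max_p = 1))
  expect_true(all(vac$selected))
})

test_that("tightening selection criteria never adds features", {
  g <- generate_cohort(cohort_design(include_post = FALSE, seed = 14))
  pm <- preprocess_expression(g$matrix)
  loose <- compare_groups(pm, g$samples,
                          criteria = selection_criteria(min_fold = 1.2, max_p = 0.2))
  tight <- compare_groups(pm, g$samples,
                          criteria = selection_criteria(min_fold = 2, max_p = 0.01))
  expect_true(all(tight$selected <= loose$selected))
  expect_true(all(selected_markers(tight)$feature_id %in%
                    selected_markers(loose)$feature_id))
  # selected list comes back sorted by p
  expect_false(is.unsorted(selected_markers(loose)$p_value))
})

test_that("paired ratios normalize each post sample to its matched pre sample", {
  v <- matrix(2^c(1, 2, 1, 2, 3, 5), 1)  # one feature, 6 samples
  samples <- data.frame(
    sample_id = c("p1-pre", "p2-pre", "p1-post", "p2-post", "p3-pre", "x-post"),
    patient_id = c("p1", "p2", "p1", "p2", "p3", "x"),
    timepoint = c("pre", "pre", "post", "post", "pre", "post"),
    response = "CR", cohort = "training", stringsAsFactors = FALSE
  )
  m <- make_em(v, sample_ids = samples$sample_id, scale = "raw-linear")
  m <- expression_matrix(log2(m$values), m$flags, "log2")
  expect_warning(r <- paired_ratio(m, samples), "p3, x")
  expect_identical(colnames(r$values), c("p1", "p2"))
  expect_equal(unname(r$values), matrix(c(0, 0), 1))  # post == pre

  # planted treatment effect of fold 2 at zero noise -> ratio exactly 1
  g <- generate_cohort(noiseless_design(seed = 2, treatment_effects = data.frame(
    feature_id = "trt", fold = 2, direction = "up", classes = "both")))
  lg <- log2_transform(floor_values(g$matrix))
  expect_warning(pr <- paired_ratio(lg, g$samples), "CLL-01")
  expect_equal(ncol(pr$values), 16L)
  expect_equal(unname(pr$values["trt", ]), rep(1, 16), tolerance = 1e-12)

  only_pre <- samples[samples$timepoint == "pre", ]
  m2 <- m[, only_pre$sample_id]
  expect_error(paired_ratio(m2, only_pre), class = "flumir_state_error")
})

test_that("percentile modulation filters match a brute-force decile oracle", {
  set.seed(5)
  n <- 20; pats <- 4
  v <- matrix(stats::rnorm(n * pats), n, pats,
              dimnames = list(sprintf("f%02d", 1:n), sprintf("p%d", 1:pats)))
  v[1, ] <- 10   # always ranked first -> up
  v[2, ] <- -10  # always ranked last -> down
  v[3, c(1, 2)] <- 8  # top decile in only 2/4 patients -> excluded
  got <- percentile_modulation_filter(make_em(v, scale = "log2"))

  k <- ceiling(n / 10)
  top_counts <- rowSums(apply(v, 2, function(col) rank(col) >= n - k + 1))
  bot_counts <- rowSums(apply(v, 2, function(col) rank(col) <= k))
  expect_setequal(got$up, rownames(v)[top_counts >= 0.75 * pats])
  expect_setequal(got$down, rownames(v)[bot_counts >= 0.75 * pats])
  expect_true("f01" %in% got$up)
  expect_true("f02" %in% got$down)
  expect_false("f03" %in% got$up)
  expect_length(intersect(got$up, got$down), 0)

  expect_error(percentile_modulation_filter(v, min_fraction = 1.5),
               class = "flumir_parameter_error")
  expect_error(percentile_modulation_filter(v[, 1, drop = FALSE]),
               class = "flumir_parameter_error")
})

test_that("Venn intersection reports the three region cardinalities", {
  v <- venn_intersect(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(v$shared, c("b", "c"))
  expect_identical(c(v$n_a_only, v$n_shared, v$n_b_only), c(1L, 2L, 1L))

  empty <- venn_intersect(c("a", "b"), c("x", "y"))
  expect_length(empty$shared, 0)

  # structural analogue of the modulated-list overlap: 67 and 60 member
  # lists sharing 37 ids
  shared <- sprintf("s%02d", 1:37)
  cr <- c(shared, sprintf("c%02d", 1:30))
  nr <- c(shared, sprintf("n%02d", 1:23))
  vv <- venn_intersect(cr, nr)
  expect_identical(c(vv$n_a_only, vv$n_shared, vv$n_b_only), c(30L, 37L, 23L))
})
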