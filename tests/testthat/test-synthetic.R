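test_that("the same design yields identical cohorts and the default structure matches the study layout", {
  d <- cohort_design(seed = 7)
  g1 <- generate_cohort(d)
  g2 <- generate_cohort(d)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$matrix$flags, g2$matrix$flags)
  expect_identical(g1$samples, g2$samples)

  expect_equal(nrow(g1$samples), 33L)
  expect_equal(sum(g1$samples$timepoint == "pre"), 17L)
  expect_equal(sum(g1$samples$timepoint == "post"), 16L)
  expect_equal(nrow(g1$matrix$values), 723L)
  expect_true(any(g1$matrix$values < 0))
  expect_true(any(!g1$matrix$flags))

  g3 <- generate_cohort(cohort_design(seed = 8))
  expect_false(identical(g1$matrix$values, g3$matrix$values))
})

test_that("zero-noise cohorts realize the planted fold changes exactly", {
  g <- generate_cohort(noiseless_design(seed = 3))
  nr <- g$samples$sample_id[g$samples$response == "NR" & g$samples$timepoint == "pre"]
  cr <- g$samples$sample_id[g$samples$response == "CR" & g$samples$timepoint == "pre"]
  v <- g$matrix$values
  ratio <- group_summary(v["hsa-miR-21*", nr]) / group_summary(v["hsa-miR-21*", cr])
  expect_equal(ratio, 3.65, tolerance = 1e-12)
  ratio_down <- group_summary(v["hsa-miR-31", nr]) / group_summary(v["hsa-miR-31", cr])
  expect_equal(ratio_down, 1 / 2.21, tolerance = 1e-12)
})

test_that("realized fold for a planted fold-2 marker is unbiased under default noise", {
  # 1000 features all planted at fold 2 give a Monte-Carlo estimate of the
  # realized NR/CR geometric-mean ratio at noise 0.4, n = 8/9
  markers <- data.frame(feature_id = sprintf("m%04d", 1:1000),
                        fold = 2, direction = "up")
  d <- cohort_design(n_features = 1000, planted_markers = markers,
                     treatment_effects = data.frame(feature_id = character(),
                                                    fold = numeric(),
                                                    direction = character(),
                                                    classes = character()),
                     include_post = FALSE, negative_rate = 0,
                     flag_absent_rate = 0, seed = 21)
  g <- generate_cohort(d)
  nr <- g$samples$sample_id[g$samples$response == "NR"]
  cr <- g$samples$sample_id[g$samples$response == "CR"]
  v <- g$matrix$values
  folds <- 2^(rowMeans(log2(v[, nr])) - rowMeans(log2(v[, cr])))
  expect_gt(mean(folds), 2 * 0.9)
  expect_lt(mean(folds), 2 * 1.1)
})

test_that("planted detectable markers sit in the top fold-change decile across replicates", {
  d0 <- cohort_design(include_post = FALSE, negative_rate = 0,
                      flag_absent_rate = 0)
  detectable <- d0$planted_markers$feature_id[d0$planted_markers$fold >= 1.5]
  hits <- 0L
  total <- 0L
  for (s in 1:200) {
    g <- generate_cohort(cohort_design(include_post = FALSE, negative_rate = 0,
                                       flag_absent_rate = 0, seed = s))
    v <- g$matrix$values
    nr <- g$samples$sample_id[g$samples$response == "NR"]
    cr <- g$samples$sample_id[g$samples$response == "CR"]
    lfc <- abs(rowMeans(log2(v[, nr])) - rowMeans(log2(v[, cr])))
    top <- names(sort(lfc, decreasing = TRUE))[seq_len(ceiling(length(lfc) / 10))]
    hits <- hits + sum(detectable %in% top)
    total <- total + length(detectable)
  }
  expect_gte(hits / total, 0.95)
})

test_that("Ct generation follows the comparative-Ct closed forms and is deterministic", {
  samples <- as_sample_info(data.frame(
    sample_id = c("a", "b"), patient_id = c("a", "b"),
    timepoint = "pre", response = c("CR", "NR"), cohort = "test"
  ))
  rel <- data.frame(response = c("CR", "NR"), target_id = "miR-x",
                    rel_expr = c(0.03125, 1))
  d <- ct_design(rel_expr = rel, replicate_ct_sd = 0, reference_ct_mean = 20,
                 reference_target = "U6", seed = 5)
  ct <- generate_ct_table(d, samples)
  ct_a_t <- ct$ct[ct$sample_id == "a" & ct$target_id == "miR-x"]
  ct_a_r <- ct$ct[ct$sample_id == "a" & ct$target_id == "U6"]
  expect_equal(unique(ct_a_t) - unique(ct_a_r), 5)    # 2^-5 = 0.03125
  ct_b_t <- ct$ct[ct$sample_id == "b" & ct$target_id == "miR-x"]
  expect_equal(unique(ct_b_t), 20)                    # rel 1 -> equals reference

  d2 <- ct_design(rel_expr = rel, seed = 9)
  expect_identical(generate_ct_table(d2, samples), generate_ct_table(d2, samples))

  bad <- as_sample_info(data.frame(sample_id = "c", patient_id = "c",
                                   timepoint = "pre", response = "NR",
                                   cohort = "test"))
  d3 <- ct_design(rel_expr = rel[rel$response == "CR", ], seed = 1)
  expect_error(generate_ct_table(d3, bad), class = "flumir_design_error")
})

test_that("design validation rejects inconsistent plants", {
  expect_error(cohort_design(planted_markers = data.frame(
    feature_id = "m", fold = 0.5, direction = "up")),
    class = "flumir_design_error")
  expect_error(cohort_design(n_features = 5),
               class = "flumir_design_error")  # fewer features than plants
  markers <- data.frame(feature_id = "dup", fold = 2, direction = "up")
  effects <- data.frame(feature_id = "dup", fold = 2, direction = "up",
                        classes = "both")
  expect_error(cohort_design(planted_markers = markers,
                             treatment_effects = effects),
               class = "flumir_design_error")
})
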