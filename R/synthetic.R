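# Synthetic cohorts with the statistical structure the analysis assumes:
# log-normal intensities (Gaussian in log2), class effects planted on NR
# samples, treatment effects planted on post samples, occasional negative raw
# values and absence flags in the low-intensity range.

default_class_markers <- function() {
  panel <- marker_reference_panel("pre")
  data.frame(feature_id = panel$mirna, fold = panel$fold_change,
             direction = panel$direction, stringsAsFactors = FALSE)
}

# Treatment-modulated features emulating the headline list structure:
# 37 features modulated in both response classes, 30 in responders only,
# 23 in non-responders only.
default_treatment_effects <- function() {
  n <- c(both = 37, CR = 30, NR = 23)
  data.frame(
    feature_id = sprintf("fl-mod-%03d", seq_len(sum(n))),
    fold = rep(c(1.8, 2.2, 2.7, 3.2), length.out = sum(n)),
    direction = rep(c("up", "down"), length.out = sum(n)),
    classes = rep(names(n), times = n),
    stringsAsFactors = FALSE
  )
}

#' Design of a synthetic CLL cohort
#'
#' Describes the cohort structure and the generative model used by
#' [generate_cohort()]: each feature's log2 intensity is
#' `baseline + class effect + treatment effect + noise`, with the class
#' effect (log2 of the planted NR/CR fold) applied to all NR samples and each
#' treatment effect (log2 of the post/pre fold) applied to post samples of
#' the classes it targets. Intensities are returned on the linear scale; a
#' small fraction of the lowest-intensity cells is made negative (background
#' over-subtraction) and low-intensity cells may be flagged absent, so the
#' preprocessing chain is exercised end to end.
#'
#' Defaults mirror the training cohort of the motivating study: 723 features,
#' 9 CR + 8 NR patients sampled pre and post treatment with one patient
#' lacking the post sample (17 + 16 = 33 arrays), class markers planted at
#' the published pre-treatment panel folds (1.18-3.65) and a baseline
#' intensity distribution spanning roughly 1 to 15,000.
#'
#' @param n_features Number of features on the platform (default 723).
#' @param n_cr,n_nr Patients per response class (defaults 9 and 8).
#' @param include_post Generate day-5 samples as well (`FALSE` for a
#'   pre-only cohort; forced for the test cohort).
#' @param n_missing_post Number of patients lacking the post sample
#'   (default 1; the unpaired case the pipeline must tolerate).
#' @param planted_markers Data frame `feature_id`, `fold` (NR/CR, >= 1),
#'   `direction` (`up`/`down` in NR relative to CR).
#' @param treatment_effects Data frame `feature_id`, `fold` (post/pre, >= 1),
#'   `direction`, `classes` (`both`, `CR` or `NR`).
#' @param baseline_log2_mean,baseline_log2_sd Location and scale of feature
#'   baseline log2 intensities (defaults 6 and 2.5).
#' @param noise_log2_sd Within-group biological noise in log2 units
#'   (default 0.4).
#' @param negative_rate Fraction of cells replaced by negative raw values
#'   (default 0.01).
#' @param flag_absent_rate Probability that a cell in the lowest intensity
#'   decile is flagged absent (default 0.3).
#' @param cohort `"training"` or `"test"`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated object of class `cohort_design`.
#' @export
cohort_design <- function(n_features = 723,
                          n_cr = 9, n_nr = 8,
                          include_post = TRUE,
                          n_missing_post = 1,
                          planted_markers = default_class_markers(),
                          treatment_effects = default_treatment_effects(),
                          baseline_log2_mean = 6,
                          baseline_log2_sd = 2.5,
                          noise_log2_sd = 0.4,
                          negative_rate = 0.01,
                          flag_absent_rate = 0.3,
                          cohort = c("training", "test"),
                          seed = 1L) {
  cohort <- match.arg(cohort)
  if (cohort == "test") {
    include_post <- FALSE
  }
  if (!include_post) n_missing_post <- 0
  stopifnot(is_count(n_features), is_count(n_cr), is_count(n_nr),
            is_count(n_missing_post), is_count(seed))
  if (n_cr + n_nr < 2L) fl_stop("need at least two patients", "flumir_design_error")
  if (n_missing_post >= n_cr + n_nr && include_post) {
    fl_stop("n_missing_post must leave at least one paired patient", "flumir_design_error")
  }
  planted_markers <- as.data.frame(planted_markers, stringsAsFactors = FALSE)
  treatment_effects <- as.data.frame(treatment_effects, stringsAsFactors = FALSE)
  check_effects <- function(df, what, need_classes = FALSE) {
    cols <- c("feature_id", "fold", "direction", if (need_classes) "classes")
    if (nrow(df) && length(setdiff(cols, colnames(df)))) {
      fl_stop(sprintf("%s needs columns %s", what, paste(cols, collapse = ", ")),
              "flumir_design_error")
    }
    if (nrow(df) && any(df$fold < 1)) {
      fl_stop(sprintf("%s folds must be >= 1", what), "flumir_design_error")
    }
    if (nrow(df) && !all(df$direction %in% c("up", "down"))) {
      fl_stop(sprintf("%s directions must be up/down", what), "flumir_design_error")
    }
    if (need_classes && nrow(df) && !all(df$classes %in% c("both", "CR", "NR"))) {
      fl_stop(sprintf("%s classes must be both/CR/NR", what), "flumir_design_error")
    }
  }
  check_effects(planted_markers, "planted_markers")
  check_effects(treatment_effects, "treatment_effects", need_classes = TRUE)
  planted_ids <- c(planted_markers$feature_id, treatment_effects$feature_id)
  if (anyDuplicated(planted_ids)) {
    fl_stop("planted marker and treatment-effect feature ids must be distinct",
            "flumir_design_error")
  }
  if (length(planted_ids) > n_features) {
    fl_stop("more planted features than n_features", "flumir_design_error")
  }
  stopifnot(baseline_log2_sd >= 0, noise_log2_sd >= 0,
            is_prob(negative_rate), is_prob(flag_absent_rate))
  structure(list(
    n_features = as.integer(n_features), n_cr = as.integer(n_cr),
    n_nr = as.integer(n_nr), include_post = isTRUE(include_post),
    n_missing_post = as.integer(n_missing_post),
    planted_markers = planted_markers, treatment_effects = treatment_effects,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd, negative_rate = negative_rate,
    flag_absent_rate = flag_absent_rate, cohort = cohort,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Generate a synthetic cohort
#'
#' Draws a raw linear-scale expression matrix, the matching sample sheet and
#' a truth table of planted effects from a [cohort_design()]. The same design
#' (same seed) always produces identical output.
#'
#' @param design A [cohort_design()].
#' @return A list with elements `matrix` (an [expression_matrix()], scale
#'   `raw-linear`), `samples` (a `sample_info` data frame) and `truth`
#'   (data frame of planted effects with a `type` column distinguishing
#'   `response_marker` from `treatment_effect` rows).
#' @export
generate_cohort <- function(design = cohort_design()) {
  if (!inherits(design, "cohort_design")) fl_stop("`design` must be a cohort_design")
  withr::with_seed(design$seed, {
    markers <- design$planted_markers
    effects <- design$treatment_effects
    planted_ids <- c(markers$feature_id, effects$feature_id)
    filler <- sprintf("miR-%04d", seq_len(design$n_features - length(planted_ids)))
    features <- c(planted_ids, filler)

    n_pat <- design$n_cr + design$n_nr
    patient_id <- sprintf("CLL-%02d", seq_len(n_pat))
    response <- rep(c("CR", "NR"), c(design$n_cr, design$n_nr))
    samples <- data.frame(
      sample_id = paste0(patient_id, "-pre"), patient_id = patient_id,
      timepoint = "pre", response = response, cohort = design$cohort,
      stringsAsFactors = FALSE
    )
    if (design$include_post) {
      # the first n_missing_post patients lack the day-5 sample
      post_pat <- seq_len(n_pat) > design$n_missing_post
      samples <- rbind(samples, data.frame(
        sample_id = paste0(patient_id[post_pat], "-post"),
        patient_id = patient_id[post_pat], timepoint = "post",
        response = response[post_pat], cohort = design$cohort,
        stringsAsFactors = FALSE
      ))
    }
    n_smp <- nrow(samples)

    baseline <- stats::rnorm(design$n_features, design$baseline_log2_mean,
                             design$baseline_log2_sd)
    lmat <- matrix(stats::rnorm(design$n_features * n_smp, 0, design$noise_log2_sd),
                   design$n_features, n_smp) + baseline
    dimnames(lmat) <- list(features, samples$sample_id)

    nr_col <- samples$response == "NR"
    if (nrow(markers)) {
      shift <- log2(markers$fold) * ifelse(markers$direction == "up", 1, -1)
      lmat[markers$feature_id, nr_col] <-
        lmat[markers$feature_id, nr_col, drop = FALSE] + shift
    }
    if (design$include_post && nrow(effects)) {
      for (i in seq_len(nrow(effects))) {
        cols <- samples$timepoint == "post" &
          (effects$classes[i] == "both" | samples$response == effects$classes[i])
        s <- log2(effects$fold[i]) * if (effects$direction[i] == "up") 1 else -1
        lmat[effects$feature_id[i], cols] <- lmat[effects$feature_id[i], cols] + s
      }
    }

    linear <- 2^lmat
    if (design$negative_rate > 0) {
      k <- round(design$negative_rate * length(linear))
      if (k > 0) {
        low <- order(linear)[seq_len(k)]
        background <- 1.05 * max(linear[low])
        linear[low] <- linear[low] - background
      }
    }
    flags <- matrix(TRUE, nrow(linear), ncol(linear), dimnames = dimnames(linear))
    if (design$flag_absent_rate > 0) {
      low_cells <- linear <= stats::quantile(linear, 0.10)
      flags[low_cells] <- stats::runif(sum(low_cells)) >= design$flag_absent_rate
    }

    truth <- rbind(
      if (nrow(markers)) cbind(markers, type = "response_marker",
                               classes = NA_character_),
      if (design$include_post && nrow(effects)) cbind(
        effects[, c("feature_id", "fold", "direction")],
        type = "treatment_effect", classes = effects$classes
      )
    )
    list(matrix = expression_matrix(linear, flags, "raw-linear"),
         samples = as_sample_info(samples),
         truth = truth)
  })
}

#' Design of a synthetic qPCR experiment
#'
#' True relative expressions (linear scale, relative to the reference target)
#' per response class and target; [generate_ct_table()] converts them to
#' replicate Ct values by `Ct = reference_ct_mean - log2(rel_expr) + noise`.
#'
#' @param rel_expr Data frame with columns `response` (CR/NR), `target_id`
#'   and `rel_expr` (> 0). The default uses the three predictor miRNAs with
#'   CR relative expression 1 and NR shifted by the published fold changes.
#' @param reference_target Reference (normalizer) target id, default
#'   `"RNU6B"`.
#' @param reference_ct_mean Mean Ct of the reference target, in cycles.
#' @param replicate_ct_sd Replicate (technical) noise sd in cycles.
#' @param n_replicates Replicates per (sample, target), default 3.
#' @param seed Integer seed.
#' @export
ct_design <- function(rel_expr = NULL, reference_target = "RNU6B",
                      reference_ct_mean = 20, replicate_ct_sd = 0.2,
                      n_replicates = 3, seed = 1L) {
  if (is.null(rel_expr)) {
    folds <- predictor_mirnas()
    rel_expr <- data.frame(
      response = rep(c("CR", "NR"), each = length(folds)),
      target_id = rep(names(folds), 2L),
      rel_expr = c(rep(1, length(folds)), unname(folds)),
      stringsAsFactors = FALSE
    )
  }
  rel_expr <- as.data.frame(rel_expr, stringsAsFactors = FALSE)
  if (length(setdiff(c("response", "target_id", "rel_expr"), colnames(rel_expr)))) {
    fl_stop("`rel_expr` needs columns response, target_id, rel_expr",
            "flumir_design_error")
  }
  if (any(rel_expr$rel_expr <= 0)) {
    fl_stop("true relative expressions must be > 0", "flumir_design_error")
  }
  stopifnot(replicate_ct_sd >= 0, is_scalar_num(reference_ct_mean),
            is_count(n_replicates), n_replicates >= 1, is_count(seed))
  structure(list(rel_expr = rel_expr, reference_target = reference_target,
                 reference_ct_mean = reference_ct_mean,
                 replicate_ct_sd = replicate_ct_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "ct_design")
}

#' Generate a synthetic Ct table for a set of samples
#'
#' @param design A [ct_design()].
#' @param samples A `sample_info` data frame; each sample's response class
#'   selects the true relative expressions. Every class present in `samples`
#'   must be covered by the design.
#' @return A [ct_table()] including reference-target rows.
#' @export
generate_ct_table <- function(design, samples) {
  if (!inherits(design, "ct_design")) fl_stop("`design` must be a ct_design")
  samples <- as_sample_info(samples)
  targets <- unique(design$rel_expr$target_id)
  classes <- unique(samples$response)
  have <- interaction(design$rel_expr$response, design$rel_expr$target_id, drop = TRUE)
  need <- as.vector(outer(classes, targets, paste, sep = "."))
  miss <- setdiff(need, levels(have))
  if (length(miss)) {
    fl_stop(sprintf("design lacks relative expression for: %s",
                    paste(miss, collapse = ", ")), "flumir_design_error")
  }
  lookup <- stats::setNames(design$rel_expr$rel_expr,
                            paste(design$rel_expr$response,
                                  design$rel_expr$target_id, sep = "."))
  withr::with_seed(design$seed, {
    rows <- vector("list", nrow(samples))
    all_targets <- c(targets, design$reference_target)
    for (i in seq_len(nrow(samples))) {
      rel <- c(lookup[paste(samples$response[i], targets, sep = ".")], 1)
      true_ct <- design$reference_ct_mean - log2(rel)
      df <- data.frame(
        sample_id = samples$sample_id[i],
        target_id = rep(all_targets, each = design$n_replicates),
        replicate = rep(seq_len(design$n_replicates), length(all_targets)),
        ct = rep(true_ct, each = design$n_replicates) +
          stats::rnorm(length(all_targets) * design$n_replicates, 0,
                       design$replicate_ct_sd),
        stringsAsFactors = FALSE
      )
      rows[[i]] <- df
    }
    ct_table(do.call(rbind, rows), reference_target = design$reference_target)
  })
}

#' Simulate per-patient relative expressions for a marker panel
#'
#' Draws log-normal relative-expression values (Gaussian in log2) for a panel
#' of markers in a two-class patient cohort: CR patients at
#' `cr_log2_mean`, NR patients shifted up by `log2(fold)` per marker. This is
#' the generative model behind the predictive-score simulations.
#'
#' @param n_cr,n_nr Patients per class.
#' @param folds Named numeric vector of NR/CR fold changes per marker
#'   (default [predictor_mirnas()]).
#' @param log2_sd Between-patient biological sd in log2 units (default 0.4).
#' @param cr_log2_mean CR-group mean of log2 relative expression (default 0,
#'   i.e. CR relative expression centred at 1).
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `response` and one column per
#'   marker holding linear relative expressions.
#' @export
simulate_marker_panel <- function(n_cr, n_nr, folds = predictor_mirnas(),
                                  log2_sd = 0.4, cr_log2_mean = 0, seed = 1L) {
  stopifnot(is_count(n_cr), is_count(n_nr), n_cr + n_nr >= 1,
            log2_sd >= 0, is_count(seed))
  if (is.null(names(folds)) || any(folds < 1)) {
    fl_stop("`folds` must be a named vector of NR/CR folds >= 1", "flumir_design_error")
  }
  withr::with_seed(seed, {
    n <- n_cr + n_nr
    response <- rep(c("CR", "NR"), c(n_cr, n_nr))
    out <- data.frame(patient_id = sprintf("PT-%02d", seq_len(n)),
                      response = response, stringsAsFactors = FALSE)
    for (m in names(folds)) {
      mu <- cr_log2_mean + ifelse(response == "NR", log2(folds[[m]]), 0)
      out[[m]] <- 2^stats::rnorm(n, mu, log2_sd)
    }
    out
  })
}
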