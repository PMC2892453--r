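# Comparative-Ct quantification: replicate aggregation, delta-Ct against the
# reference gene and 2^-deltaCt relative expression, plus two-group
# comparison of relative expressions.

#' Aggregate replicate Ct measurements
#'
#' Arithmetic mean and sample standard deviation of the replicate Ct values
#' for every (sample, target) pair; Ct values (not linear quantities) are
#' averaged, the standard comparative-Ct practice. A single replicate yields
#' `sd_ct = NA`.
#'
#' @param ct A [ct_table()].
#' @return Data frame with columns `sample_id`, `target_id`, `n_replicates`,
#'   `mean_ct`, `sd_ct` (first-occurrence order).
#' @export
aggregate_replicates <- function(ct) {
  if (!inherits(ct, "ct_table")) fl_stop("`ct` must be a ct_table")
  key <- paste(ct$sample_id, ct$target_id, sep = "\r")
  idx <- split(seq_len(nrow(ct)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    data.frame(
      sample_id = ct$sample_id[i[1L]], target_id = ct$target_id[i[1L]],
      n_replicates = length(i), mean_ct = mean(ct$ct[i]),
      sd_ct = if (length(i) > 1L) stats::sd(ct$ct[i]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the comparative-Ct (2^-deltaCt) method
#'
#' For every non-reference target in every sample: `delta_ct = mean_ct -
#' reference_mean_ct` and `rel_expr = 2^-delta_ct`, i.e. target abundance
#' normalized on the reference gene (e.g. U6). `log2(rel_expr)` equals
#' `-delta_ct` exactly, and `rel_expr = 1` iff target and reference
#' amplify at the same cycle.
#'
#' @param ct A [ct_table()] (its `reference_target` attribute names the
#'   normalizer).
#' @return Data frame of class `relative_expression` with columns
#'   `sample_id`, `target_id`, `mean_ct`, `replicate_sd`,
#'   `reference_mean_ct`, `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct) {
  if (!inherits(ct, "ct_table")) fl_stop("`ct` must be a ct_table")
  refid <- attr(ct, "reference_target")
  agg <- aggregate_replicates(ct)
  ref <- agg[agg$target_id == refid, , drop = FALSE]
  tgt <- agg[agg$target_id != refid, , drop = FALSE]
  ref_mean <- stats::setNames(ref$mean_ct, ref$sample_id)
  if (anyNA(ref_mean[tgt$sample_id])) {
    fl_stop(sprintf("reference target '%s' missing for sample(s): %s", refid,
                    paste(unique(tgt$sample_id[is.na(ref_mean[tgt$sample_id])]),
                          collapse = ", ")),
            "flumir_data_error")
  }
  out <- data.frame(
    sample_id = tgt$sample_id, target_id = tgt$target_id,
    mean_ct = tgt$mean_ct, replicate_sd = tgt$sd_ct,
    reference_mean_ct = unname(ref_mean[tgt$sample_id]),
    stringsAsFactors = FALSE
  )
  out$delta_ct <- out$mean_ct - out$reference_mean_ct
  out$rel_expr <- 2^(-out$delta_ct)
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Two-group comparison of relative expressions
#'
#' Two-tailed Welch t-test between the relative expressions of two patient
#' groups. The default log2 scale (equivalently a test on -delta_ct) is
#' appropriate for log-normally distributed expression; `"linear"` tests
#' the raw 2^-deltaCt values.
#'
#' @param group_a,group_b Positive relative-expression values, each group of
#'   length >= 2.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return The two-tailed p-value.
#' @export
compare_rel_expr <- function(group_a, group_b, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    fl_stop("each group needs at least 2 values", "flumir_parameter_error")
  }
  if (any(group_a <= 0) || any(group_b <= 0)) {
    fl_stop("relative expressions must be positive", "flumir_parameter_error")
  }
  if (scale == "log2") {
    group_a <- log2(group_a)
    group_b <- log2(group_b)
  }
  welch_test(group_a, group_b)
}
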