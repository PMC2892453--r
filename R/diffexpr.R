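# Two-group differential expression: fold change between group geometric
# means plus a Welch t-test on log2 values, with optional Benjamini-Hochberg
# adjustment, paired post/pre log-ratios, percentile modulation filters and
# Venn intersection of marker lists.

#' Geometric mean of linear intensities
#'
#' The group summary behind all fold changes: `2^mean(log2(values))`,
#' i.e. the geometric mean on the linear scale (equivalently the arithmetic
#' mean in log2).
#'
#' @param values Positive linear-scale intensities of one feature in one
#'   group (non-empty).
#' @export
group_summary <- function(values) {
  if (!length(values)) fl_stop("group is empty", "flumir_parameter_error")
  if (any(!is.finite(values)) || any(values <= 0)) {
    fl_stop("group summary requires finite positive linear values",
            "flumir_parameter_error")
  }
  2^mean(log2(values))
}

#' Absolute fold change and direction between two group summaries
#'
#' Absolute fold = larger/smaller of the two summaries; direction is `up`
#' when group A exceeds group B (equal summaries are reported as `up` with
#' fold 1 by convention). Vectorized over both arguments.
#'
#' @param summary_a,summary_b Positive linear group summaries (e.g. NR and
#'   CR geometric means).
#' @return Data frame with columns `fold_change` and `direction`.
#' @export
fold_change <- function(summary_a, summary_b) {
  if (any(!is.finite(summary_a)) || any(!is.finite(summary_b)) ||
      any(summary_a <= 0) || any(summary_b <= 0)) {
    fl_stop("group summaries must be finite and positive", "flumir_parameter_error")
  }
  data.frame(
    fold_change = pmax(summary_a, summary_b) / pmin(summary_a, summary_b),
    direction = ifelse(summary_a >= summary_b, "up", "down"),
    stringsAsFactors = FALSE
  )
}

# Vectorized Welch test over matrix rows. x: matrix; a, b: column indices.
# Degenerate rows (zero pooled variance): p = 1 when the means agree, else
# the smallest positive double (the zero-noise limit, kept > 0 so that
# p-values remain in (0, 1]).
row_welch <- function(x, a, b) {
  n1 <- length(a); n2 <- length(b)
  xa <- x[, a, drop = FALSE]; xb <- x[, b, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  deg <- se2 == 0
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  if (any(deg)) {
    p[deg] <- ifelse(m1[deg] == m2[deg], 1, .Machine$double.xmin)
  }
  p
}

#' Welch two-sample t-test p-value
#'
#' Two-tailed p-value from the unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom, computed on log2 values. Both
#' groups constant and equal gives p = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors of log2 values, each of length
#'   >= 2.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    fl_stop("each group needs at least 2 values", "flumir_parameter_error")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    fl_stop("groups must contain finite values only", "flumir_parameter_error")
  }
  x <- matrix(c(group_a, group_b), nrow = 1L)
  row_welch(x, seq_along(group_a), length(group_a) + seq_along(group_b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, order preserved, capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) && (any(!is.finite(p_values)) ||
                           any(p_values < 0) || any(p_values > 1))) {
    fl_stop("p-values must lie in [0, 1]", "flumir_parameter_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Marker selection criteria
#'
#' @param min_fold Minimum absolute fold change (default 1.5).
#' @param max_p Significance cutoff; features with p (or q) below it are
#'   selected. A value of 1 (or more) disables the p filter entirely, as in
#'   noise-free recovery checks. Default 0.05.
#' @param use_q Apply the cutoff to BH-adjusted q-values instead of raw
#'   p-values (default `FALSE`, the miRNA convention; mRNA analyses
#'   typically set `TRUE`).
#' @export
selection_criteria <- function(min_fold = 1.5, max_p = 0.05, use_q = FALSE) {
  if (!is_scalar_num(min_fold) || min_fold < 1) {
    fl_stop("`min_fold` must be >= 1", "flumir_parameter_error")
  }
  if (!is_scalar_num(max_p) || max_p <= 0) {
    fl_stop("`max_p` must be positive", "flumir_parameter_error")
  }
  structure(list(min_fold = min_fold, max_p = max_p, use_q = isTRUE(use_q)),
            class = "selection_criteria")
}

#' Two-group differential expression over all features
#'
#' For every feature: linear-scale geometric-mean summaries of the two
#' groups (computed by back-transforming the log2 matrix), absolute fold
#' change with direction of group A relative to group B, a two-tailed Welch
#' p-value on the log2 values, and its BH-adjusted q-value. A feature is
#' `selected` when its fold change reaches `min_fold` and its p (or q, with
#' `use_q`) falls below `max_p`.
#'
#' @param m Log2-scale [expression_matrix()].
#' @param samples `sample_info` rows covering (at least) the matrix columns.
#' @param group_by Metadata column to group on (`"response"` or
#'   `"timepoint"`).
#' @param group_a,group_b The two levels to compare; fold direction is A
#'   over B (e.g. NR over CR).
#' @param criteria A [selection_criteria()].
#' @return Data frame of class `diffexpr_result` with one row per feature
#'   (input order) and columns `feature_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `direction`, `p_value`, `q_value`, `selected`.
#'   Use [selected_markers()] for the selected subset sorted by p-value.
#' @export
compare_groups <- function(m, samples, group_by = "response",
                           group_a = "NR", group_b = "CR",
                           criteria = selection_criteria()) {
  if (!inherits(m, "expr_matrix")) fl_stop("`m` must be an expr_matrix")
  if (m$scale != "log2") {
    fl_stop("compare_groups requires a log2-scale matrix", "flumir_state_error")
  }
  if (!inherits(criteria, "selection_criteria")) {
    fl_stop("`criteria` must be a selection_criteria object", "flumir_parameter_error")
  }
  samples <- as_sample_info(samples)
  if (!group_by %in% colnames(samples)) {
    fl_stop(sprintf("no metadata column '%s'", group_by), "flumir_parameter_error")
  }
  samples <- samples[samples$sample_id %in% colnames(m$values), , drop = FALSE]
  ids_a <- samples$sample_id[samples[[group_by]] == group_a]
  ids_b <- samples$sample_id[samples[[group_by]] == group_b]
  if (!length(ids_a) || !length(ids_b)) {
    fl_stop(sprintf("selector %s = '%s' matches no samples", group_by,
                    if (length(ids_a)) group_b else group_a),
            "flumir_parameter_error")
  }
  a <- match(ids_a, colnames(m$values))
  b <- match(ids_b, colnames(m$values))
  la <- rowMeans(m$values[, a, drop = FALSE])
  lb <- rowMeans(m$values[, b, drop = FALSE])
  fc <- fold_change(2^la, 2^lb)
  p <- if (length(a) >= 2L && length(b) >= 2L) {
    row_welch(m$values, a, b)
  } else {
    fl_stop("each group needs at least 2 samples for the Welch test",
            "flumir_parameter_error")
  }
  q <- bh_adjust(p)
  stat <- if (criteria$use_q) q else p
  selected <- fc$fold_change >= criteria$min_fold &
    (criteria$max_p >= 1 | stat < criteria$max_p)
  res <- data.frame(
    feature_id = rownames(m$values),
    mean_a = 2^la, mean_b = 2^lb,
    fold_change = fc$fold_change, direction = fc$direction,
    p_value = p, q_value = q, selected = selected,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "group_by") <- group_by
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  attr(res, "criteria") <- criteria
  class(res) <- c("diffexpr_result", "data.frame")
  res
}

#' Selected markers of a differential-expression result
#'
#' @param res A `diffexpr_result` from [compare_groups()].
#' @return The selected rows sorted by increasing p-value.
#' @export
selected_markers <- function(res) {
  if (!inherits(res, "diffexpr_result")) fl_stop("`res` must be a diffexpr_result")
  out <- res[res$selected, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Per-patient post/pre log-ratios
#'
#' Normalizes each post-treatment sample to its matched pre-treatment sample
#' patient by patient: one output column per complete patient holding
#' `log2(post) - log2(pre)` per feature. Patients lacking either timepoint
#' are dropped with a warning.
#'
#' @param m Log2-scale [expression_matrix()].
#' @param samples `sample_info` rows covering the matrix columns.
#' @return An [expression_matrix()] of log2-ratios (scale `"log2"`), columns
#'   named by patient id.
#' @export
paired_ratio <- function(m, samples) {
  if (!inherits(m, "expr_matrix") || m$scale != "log2") {
    fl_stop("paired_ratio requires a log2-scale expr_matrix", "flumir_state_error")
  }
  samples <- as_sample_info(samples)
  samples <- samples[samples$sample_id %in% colnames(m$values), , drop = FALSE]
  pre <- samples[samples$timepoint == "pre", ]
  post <- samples[samples$timepoint == "post", ]
  patients <- intersect(pre$patient_id, post$patient_id)
  unpaired <- setdiff(unique(samples$patient_id), patients)
  if (!length(patients)) {
    fl_stop("no patient has both a pre and a post sample", "flumir_state_error")
  }
  if (length(unpaired)) {
    warning(sprintf("dropping %d patient(s) without a complete pre/post pair: %s",
                    length(unpaired), paste(unpaired, collapse = ", ")))
  }
  pre_id <- pre$sample_id[match(patients, pre$patient_id)]
  post_id <- post$sample_id[match(patients, post$patient_id)]
  ratio <- m$values[, post_id, drop = FALSE] - m$values[, pre_id, drop = FALSE]
  colnames(ratio) <- patients
  expression_matrix(ratio, scale = "log2")
}

#' Percentile modulation filter on paired ratios
#'
#' Ranks features within each patient column of a [paired_ratio()] matrix
#' and reports the features sitting in the top decile (90th-100th
#' percentile) of their column in at least `min_fraction` of patients
#' (up-modulated) and, analogously, in the bottom decile (0-10th percentile;
#' down-modulated). The decile holds the `ceiling(n/10)` most extreme ranks,
#' which keeps it non-empty for small feature counts.
#'
#' @param ratios [expression_matrix()] of per-patient log-ratios (or a plain
#'   numeric matrix) with at least 2 columns.
#' @param min_fraction Minimum fraction of patients, in (0, 1]; default 0.75.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
percentile_modulation_filter <- function(ratios, min_fraction = 0.75) {
  v <- if (inherits(ratios, "expr_matrix")) ratios$values else ratios
  if (!is.matrix(v) || !is.numeric(v)) fl_stop("`ratios` must be a numeric matrix")
  if (ncol(v) < 2L) fl_stop("need ratios for at least 2 patients", "flumir_parameter_error")
  if (!is_scalar_num(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    fl_stop("`min_fraction` must lie in (0, 1]", "flumir_parameter_error")
  }
  n <- nrow(v)
  k <- ceiling(n / 10)
  r <- apply(v, 2L, rank, ties.method = "first")
  if (!is.matrix(r)) r <- matrix(r, nrow = n)
  need <- min_fraction * ncol(v) - 1e-9
  up_ids <- rownames(v)[rowSums(r >= n - k + 1L) >= need]
  down_ids <- rownames(v)[rowSums(r <= k) >= need]
  overlap <- intersect(up_ids, down_ids)
  if (length(overlap)) {
    warning(sprintf("feature(s) qualifying as both up- and down-modulated dropped: %s",
                    paste(overlap, collapse = ", ")))
    up_ids <- setdiff(up_ids, overlap)
    down_ids <- setdiff(down_ids, overlap)
  }
  list(up = up_ids, down = down_ids)
}

#' Venn intersection of two marker lists
#'
#' @param list_a,list_b Character vectors of feature ids (duplicates are
#'   ignored).
#' @return Object of class `venn_overlap`: list with `shared`, `a_only`,
#'   `b_only` and the three region cardinalities `n_a_only`, `n_shared`,
#'   `n_b_only`.
#' @export
venn_intersect <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  shared <- intersect(a, b)
  structure(list(
    shared = shared, a_only = setdiff(a, b), b_only = setdiff(b, a),
    n_a_only = length(setdiff(a, b)), n_shared = length(shared),
    n_b_only = length(setdiff(b, a))
  ), class = "venn_overlap")
}

#' @export
print.venn_overlap <- function(x, ...) {
  cat(sprintf("<venn_overlap> A-only: %d | shared: %d | B-only: %d\n",
              x$n_a_only, x$n_shared, x$n_b_only))
  invisible(x)
}
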