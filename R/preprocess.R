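# Preprocessing chain for single-channel array intensities. The pipeline
# order is fixed: floor -> quantile normalization -> log2 -> presence filter;
# the order matters and is enforced through the scale tag.

check_linear <- function(m, op) {
  if (!inherits(m, "expr_matrix")) fl_stop(sprintf("%s expects an expr_matrix", op))
  if (!m$scale %in% c("raw-linear", "normalized-linear")) {
    fl_stop(sprintf("%s requires a linear-scale matrix (got scale '%s')", op, m$scale),
            class = "flumir_state_error")
  }
  invisible(m)
}

#' Floor low and negative intensities
#'
#' Replaces every value below `floor` by `floor`. Background subtraction in
#' array feature extraction can leave negative raw intensities; flooring at
#' 1.0 both removes them and guarantees non-negative log2 values. The
#' faithful "negatives only" rule is available by passing a floor just above
#' zero.
#'
#' @param m Linear-scale [expression_matrix()].
#' @param floor Intensity floor, default 1.0.
#' @return The floored matrix; flags unchanged.
#' @export
floor_values <- function(m, floor = 1.0) {
  check_linear(m, "floor_values")
  stopifnot(is_scalar_num(floor), floor > 0)
  v <- m$values
  v[v < floor] <- floor
  expression_matrix(v, m$flags, m$scale)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the common reference distribution formed
#' by averaging same-rank values across columns, reassigned by each column's
#' original ranks, so all columns end up with (essentially) identical
#' empirical distributions.
#'
#' Two tie dialects are provided. `"average"` (default, the usual convention,
#' matching `limma::normalizeQuantiles`): tied values share the mean of the
#' reference values at their tied rank positions, so ties stay tied.
#' `"first"`: ties are split by position, making every column an exact
#' permutation of the reference distribution; under this dialect the column
#' distributions are identical as multisets for any input and the operation
#' is exactly idempotent, properties that tie averaging necessarily gives up
#' on tied data (the averaged value does not occur in tie-free columns).
#'
#' @param m Linear-scale [expression_matrix()] with at least 2 samples (a
#'   single-sample matrix is returned unchanged with a warning).
#' @param ties `"average"` or `"first"` (see Details).
#' @return The normalized matrix with scale `"normalized-linear"`.
#' @export
quantile_normalize <- function(m, ties = c("average", "first")) {
  ties <- match.arg(ties)
  check_linear(m, "quantile_normalize")
  v <- m$values
  if (ncol(v) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(m)
  }
  sorted <- apply(v, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = nrow(v))
  ref <- rowMeans(sorted)
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    y <- ref[rank(col, ties.method = "first")]
    if (ties == "average" && anyDuplicated(col)) {
      y <- stats::ave(y, match(col, col), FUN = mean)
    }
    out[, j] <- y
  }
  expression_matrix(out, m$flags, "normalized-linear")
}

#' Log2 transform
#'
#' @param m Linear-scale [expression_matrix()] with strictly positive values
#'   (run [floor_values()] first).
#' @return The matrix in log2 units (scale `"log2"`).
#' @export
log2_transform <- function(m) {
  check_linear(m, "log2_transform")
  if (any(m$values <= 0)) {
    fl_stop("non-positive values present; apply floor_values() before log2_transform()",
            class = "flumir_state_error")
  }
  expression_matrix(log2(m$values), m$flags, "log2")
}

#' Filter features on presence calls
#'
#' Keeps features flagged present (`P`) in at least `min_present` samples;
#' the default of 1 retains anything expressed in at least one sample.
#' Feature order is preserved.
#'
#' @param m An [expression_matrix()] with flags.
#' @param min_present Minimum number of present calls (default 1).
#' @export
presence_filter <- function(m, min_present = 1) {
  if (!inherits(m, "expr_matrix")) fl_stop("presence_filter expects an expr_matrix")
  if (!is_count(min_present) || min_present < 1 || min_present > ncol(m$values)) {
    fl_stop(sprintf("`min_present` must be in 1..%d", ncol(m$values)),
            class = "flumir_parameter_error")
  }
  keep <- rowSums(m$flags) >= min_present
  m[keep, ]
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: [floor_values()], [quantile_normalize()],
#' [log2_transform()], [presence_filter()].
#'
#' @param m Raw linear [expression_matrix()].
#' @inheritParams floor_values
#' @inheritParams presence_filter
#' @inheritParams quantile_normalize
#' @return A log2-scale, presence-filtered matrix ready for statistics.
#' @export
preprocess_expression <- function(m, floor = 1.0, min_present = 1,
                                  ties = "average") {
  m <- floor_values(m, floor = floor)
  m <- quantile_normalize(m, ties = ties)
  m <- log2_transform(m)
  presence_filter(m, min_present = min_present)
}
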