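# Hierarchical clustering of samples on a selected marker list, and the
# accuracy of a two-way cut against known response labels.

#' Center features on their across-sample mean
#'
#' Subtracts each feature row's mean, the usual display/clustering
#' normalization ("expression relative to the miRNA's mean across all
#' samples").
#'
#' @param m Log2-scale [expression_matrix()].
#' @export
center_features <- function(m) {
  if (!inherits(m, "expr_matrix") || m$scale != "log2") {
    fl_stop("center_features requires a log2-scale expr_matrix", "flumir_state_error")
  }
  expression_matrix(m$values - rowMeans(m$values), m$flags, "log2")
}

#' Agglomerative clustering of samples
#'
#' Complete-linkage agglomeration on Manhattan (city-block) distances
#' between samples, computed on the selected features. "Manhattan
#' correlation", as some array suites label their similarity option, is
#' interpreted as plain city-block distance: no standard statistic of that
#' name exists.
#'
#' @param m Log2-scale [expression_matrix()] (typically centered via
#'   [center_features()]).
#' @param features Optional character vector restricting clustering to a
#'   marker list; must be non-empty and present in the matrix.
#' @param distance Distance measure; only `"manhattan"` is offered.
#' @param linkage Linkage rule; only `"complete"` is offered.
#' @return Object of class `sample_clustering`: list with the `hclust` merge
#'   tree, `sample_ids`, and the feature count used.
#' @export
cluster_samples <- function(m, features = NULL, distance = "manhattan",
                            linkage = "complete") {
  if (!inherits(m, "expr_matrix")) fl_stop("`m` must be an expr_matrix")
  distance <- match.arg(distance, "manhattan")
  linkage <- match.arg(linkage, "complete")
  v <- m$values
  if (!is.null(features)) {
    if (!length(features)) fl_stop("empty feature list", "flumir_parameter_error")
    miss <- setdiff(features, rownames(v))
    if (length(miss)) {
      fl_stop(sprintf("feature(s) not in matrix: %s", paste(miss, collapse = ", ")),
              "flumir_parameter_error")
    }
    v <- v[features, , drop = FALSE]
  }
  if (ncol(v) < 2L) fl_stop("need at least 2 samples", "flumir_parameter_error")
  d <- stats::dist(t(v), method = "manhattan")
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, sample_ids = colnames(v), n_features = nrow(v)),
            class = "sample_clustering")
}

#' Accuracy of a two-group cut against known labels
#'
#' Cuts the sample tree into two clusters and scores the fraction of samples
#' whose cluster matches their true class under the better of the two
#' cluster-to-class assignments (so chance level for balanced labels is at
#' least 0.5).
#'
#' @param cl A [cluster_samples()] result.
#' @param truth Named character vector of class labels (names = sample ids),
#'   or a `sample_info` data frame whose `response` column is used.
#' @return Object of class `cluster_evaluation`: list with `accuracy`,
#'   `misclassified` sample ids, the per-sample `cluster` assignment and the
#'   cluster-to-class `mapping` used.
#' @export
evaluate_two_group_cut <- function(cl, truth) {
  if (!inherits(cl, "sample_clustering")) fl_stop("`cl` must be a sample_clustering")
  if (inherits(truth, "sample_info") || is.data.frame(truth)) {
    truth <- stats::setNames(truth$response, truth$sample_id)
  }
  labels <- truth[cl$sample_ids]
  if (anyNA(labels)) {
    fl_stop(sprintf("labels missing for sample(s): %s",
                    paste(cl$sample_ids[is.na(labels)], collapse = ", ")),
            "flumir_parameter_error")
  }
  classes <- sort(unique(unname(labels)))
  if (length(classes) != 2L) {
    fl_stop("two-group evaluation needs exactly 2 distinct labels",
            "flumir_parameter_error")
  }
  cut2 <- stats::cutree(cl$hclust, k = 2)
  if (length(unique(cut2)) < 2L) {
    warning("degenerate tree: the two-group cut produced a single cluster")
  }
  maps <- list(stats::setNames(classes, 1:2), stats::setNames(rev(classes), 1:2))
  accs <- vapply(maps, function(mp) mean(mp[as.character(cut2)] == labels), 0)
  best <- which.max(accs)
  pred <- maps[[best]][as.character(cut2)]
  structure(list(
    accuracy = accs[best],
    misclassified = cl$sample_ids[pred != labels],
    cluster = stats::setNames(unname(cut2), cl$sample_ids),
    mapping = maps[[best]]
  ), class = "cluster_evaluation")
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  cat(sprintf("<cluster_evaluation> accuracy %.1f%% (%d misclassified)\n",
              100 * x$accuracy, length(x$misclassified)))
  if (length(x$misclassified)) {
    cat("  misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  }
  invisible(x)
}
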