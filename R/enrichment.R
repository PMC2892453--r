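# Over-representation analysis of a selected gene list against gene-set
# collections, reported in the platform-background style: set size, members
# matched with the technology (background), members matched with the
# selected list, and an upper-tail hypergeometric p-value.

#' Hypergeometric over-representation analysis
#'
#' For every set: `k` = members in the selected list, `K` = members in the
#' background (features present on the platform), `N` = background size,
#' `n` = selected-list size; the p-value is the upper-tail hypergeometric
#' probability `P(X >= k)` of drawing at least `k` set members in `n` draws
#' without replacement from `N` features of which `K` belong to the set.
#' Raw p-values match the usual reporting style for this analysis; a
#' BH-adjusted column is emitted alongside for transparency.
#'
#' @param selected Character vector of selected feature ids (must be a
#'   subset of `background`).
#' @param background Character vector of background feature ids (non-empty).
#' @param sets A [gene_sets()] collection.
#' @return Data frame of class `enrichment_result`, sorted by increasing
#'   p-value, with columns `set_name`, `n_entities`, `n_matched_technology`,
#'   `n_matched_list`, `p_value`, `q_value`.
#' @export
enrich <- function(selected, background, sets) {
  if (!inherits(sets, "gene_sets")) fl_stop("`sets` must be a gene_sets collection")
  background <- unique(as.character(background))
  selected <- unique(as.character(selected))
  if (!length(background)) fl_stop("background is empty")
  extra <- setdiff(selected, background)
  if (length(extra)) {
    fl_stop(sprintf("selected id(s) not in background: %s",
                    paste(utils::head(extra, 5L), collapse = ", ")))
  }
  N <- length(background)
  n <- length(selected)
  K <- vapply(sets, function(s) length(intersect(s, background)), 0L)
  k <- vapply(sets, function(s) length(intersect(s, selected)), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    set_name = names(sets), n_entities = lengths(sets),
    n_matched_technology = K, n_matched_list = k,
    p_value = p, q_value = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enrichment records on significance
#'
#' @param records An [enrich()] result (or any data frame with a `p_value`
#'   column).
#' @param max_p Keep records with `p_value < max_p` (default 0.05); order
#'   preserved.
#' @export
filter_enrichment <- function(records, max_p = 0.05) {
  if (!is.data.frame(records) || !"p_value" %in% colnames(records)) {
    fl_stop("`records` must be a data frame with a p_value column")
  }
  records[records$p_value < max_p, , drop = FALSE]
}
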