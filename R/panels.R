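#' Reference miRNA marker panels for fludarabine response
#'
#' Published per-marker summaries of the miRNAs differentially expressed
#' between refractory (NR) and responder (CR) CLL patients, before (`pre`)
#' or after (`post`) a five-day fludarabine course: Welch p-value, absolute
#' fold change, regulation of NR relative to CR, and the NR and CR group
#' geometric-mean expressions on the linear intensity scale. These panels
#' drive the default planted effect sizes of [cohort_design()] and serve as
#' in-package worked examples for [fold_change()].
#'
#' @param timepoint `"pre"` or `"post"` treatment comparison.
#' @return A data frame with columns `mirna`, `p_value`, `fold_change`,
#'   `direction`, `nr_mean`, `cr_mean`, `chromosome`, `accession`.
#' @export
marker_reference_panel <- function(timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  path <- system.file("extdata", sprintf("mirna_markers_%s.tsv", timepoint),
                      package = "flumir", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' The three qPCR-validated predictor miRNAs
#'
#' miR-21, miR-148a and miR-222 are up-regulated in refractory patients both
#' before and after treatment and form the marker panel of the predictive
#' score. The returned named vector maps each marker to its pre-treatment
#' NR/CR absolute fold change, used as the default planted effect size in
#' score-related simulations.
#'
#' @return Named numeric vector of NR/CR fold changes.
#' @export
predictor_mirnas <- function() {
  c("hsa-miR-21" = 3.65, "hsa-miR-148a" = 3.44, "hsa-miR-222" = 2.12)
}
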