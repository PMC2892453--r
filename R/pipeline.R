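# End-to-end orchestration of the study workflow: the training-cohort
# discovery analysis and the test-cohort score prediction. Both are
# deterministic given their inputs; when an output directory is supplied,
# result tables plus a JSON manifest (parameters, seed, counts, output
# checksums) are written so a run can be audited and reproduced.

#' Training-cohort discovery analysis
#'
#' Runs the full discovery workflow on a training cohort:
#' preprocessing (floor, quantile normalization, log2, presence filter);
#' post-vs-pre differential expression in all patients, in responders (CR)
#' and in non-responders (NR) separately; Venn intersection of the CR- and
#' NR-modulated lists; NR-vs-CR differential expression at each timepoint;
#' and complete-linkage clustering of the samples on each selected marker
#' list with two-group classification accuracy against the response labels.
#'
#' @param expr Raw linear [expression_matrix()].
#' @param samples `sample_info` for the matrix columns (training cohort).
#' @param criteria [selection_criteria()] applied to every comparison.
#' @param floor,min_present Preprocessing parameters (see
#'   [preprocess_expression()]).
#' @param out_dir Optional directory: result tables and `manifest.json` are
#'   written there.
#' @param seed Optional integer recorded in the manifest (the analysis
#'   itself is deterministic; the seed documents how the inputs were
#'   generated).
#' @return List with elements `preprocessed`, `treatment` (post-vs-pre
#'   results: `all`, `cr`, `nr`), `venn`, `response` (NR-vs-CR results:
#'   `pre`, `post`), `clustering` (`pre`, `post`; `NULL` when no marker was
#'   selected), and `counts` (the in/out tally of every filter).
#' @export
run_training_analysis <- function(expr, samples,
                                  criteria = selection_criteria(),
                                  floor = 1.0, min_present = 1,
                                  out_dir = NULL, seed = NULL) {
  if (!inherits(expr, "expr_matrix")) fl_stop("`expr` must be an expr_matrix")
  samples <- as_sample_info(samples)
  pm <- preprocess_expression(expr, floor = floor, min_present = min_present)

  cmp_tp <- function(s) {
    compare_groups(pm, s, group_by = "timepoint", group_a = "post",
                   group_b = "pre", criteria = criteria)
  }
  trt_all <- cmp_tp(samples)
  trt_cr <- cmp_tp(samples[samples$response == "CR", , drop = FALSE])
  trt_nr <- cmp_tp(samples[samples$response == "NR", , drop = FALSE])
  venn <- venn_intersect(selected_markers(trt_cr)$feature_id,
                         selected_markers(trt_nr)$feature_id)

  cmp_resp <- function(tp) {
    compare_groups(pm, samples[samples$timepoint == tp, , drop = FALSE],
                   group_by = "response", group_a = "NR", group_b = "CR",
                   criteria = criteria)
  }
  resp_pre <- cmp_resp("pre")
  resp_post <- cmp_resp("post")

  clust_eval <- function(res, tp) {
    ids <- selected_markers(res)$feature_id
    if (!length(ids)) {
      message(sprintf("no markers selected for the %s-treatment comparison; clustering skipped", tp))
      return(NULL)
    }
    ss <- samples[samples$timepoint == tp, , drop = FALSE]
    msub <- pm[, colnames(pm$values) %in% ss$sample_id]
    cl <- cluster_samples(center_features(msub), features = ids)
    evaluate_two_group_cut(cl, ss)
  }
  cl_pre <- clust_eval(resp_pre, "pre")
  cl_post <- clust_eval(resp_post, "post")

  counts <- list(
    features_in = nrow(expr$values),
    features_after_presence_filter = nrow(pm$values),
    samples = ncol(pm$values),
    treatment_selected = c(all = sum(trt_all$selected),
                           cr = sum(trt_cr$selected),
                           nr = sum(trt_nr$selected)),
    treatment_shared = venn$n_shared,
    response_selected = c(pre = sum(resp_pre$selected),
                          post = sum(resp_post$selected))
  )

  result <- list(
    preprocessed = pm,
    treatment = list(all = trt_all, cr = trt_cr, nr = trt_nr),
    venn = venn,
    response = list(pre = resp_pre, post = resp_post),
    clustering = list(pre = cl_pre, post = cl_post),
    counts = counts
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(
      "treatment_post_vs_pre_all.tsv" = trt_all,
      "treatment_post_vs_pre_cr.tsv" = trt_cr,
      "treatment_post_vs_pre_nr.tsv" = trt_nr,
      "response_nr_vs_cr_pre.tsv" = resp_pre,
      "response_nr_vs_cr_post.tsv" = resp_post
    )
    for (nm in names(tables)) {
      write_results_table(as.data.frame(tables[[nm]]), file.path(out_dir, nm))
    }
    writeLines(venn$shared, file.path(out_dir, "treatment_shared_markers.txt"))
    manifest <- list(
      analysis = "training",
      parameters = list(floor = floor, min_present = min_present,
                        criteria = unclass(criteria)),
      seed = seed,
      counts = counts,
      outputs = as.list(tools::md5sum(file.path(out_dir, c(names(tables),
                                                           "treatment_shared_markers.txt"))))
    )
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Test-cohort response prediction
#'
#' Quantifies marker expression by the comparative-Ct method (when a Ct
#' table is supplied), scores every patient with a calibrated
#' [calibrate_score()] model, and — when true classes are available —
#' reports the confusion table and accuracy.
#'
#' @param model A calibrated `score_model`.
#' @param ct Optional [ct_table()] of the test cohort (one sample per
#'   patient); its relative expressions feed the score.
#' @param expressions Optional per-patient relative-expression table
#'   (columns = model markers) used directly instead of `ct`.
#' @param truth Optional CR/NR labels, aligned with the patients or named
#'   by patient id.
#' @param out_dir Optional directory for the per-patient report and
#'   manifest.
#' @return List with `relative_expression` (or `NULL`), `scores` and
#'   `evaluation` (or `NULL` when no truth given).
#' @export
run_prediction <- function(model, ct = NULL, expressions = NULL, truth = NULL,
                           out_dir = NULL) {
  if (!inherits(model, "score_model")) fl_stop("`model` must be a score_model")
  rel <- NULL
  if (is.null(expressions)) {
    if (is.null(ct)) fl_stop("supply either `ct` or `expressions`",
                             "flumir_parameter_error")
    rel <- relative_expression(ct)
    sample_ids <- unique(rel$sample_id)
    wide <- vapply(model$markers, function(m) {
      v <- rel$rel_expr[rel$target_id == m][match(sample_ids,
                                                  rel$sample_id[rel$target_id == m])]
      v
    }, numeric(length(sample_ids)))
    if (!is.matrix(wide)) wide <- matrix(wide, nrow = length(sample_ids))
    colnames(wide) <- model$markers
    if (anyNA(wide)) {
      fl_stop("marker measurements missing for some sample(s)", "flumir_data_error")
    }
    expressions <- data.frame(patient_id = sample_ids, wide,
                              check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!nrow(as.data.frame(expressions))) {
    fl_stop("empty cohort", "flumir_parameter_error")
  }
  scores <- score_patients(model, expressions)
  evaluation <- if (!is.null(truth)) evaluate_score(model, expressions, truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(rel)) {
      write_results_table(as.data.frame(rel), file.path(out_dir, "relative_expression.tsv"))
    }
    report <- if (!is.null(evaluation)) evaluation$predictions else scores
    write_results_table(report, file.path(out_dir, "score_predictions.tsv"))
    write_score_model(model, file.path(out_dir, "score_model.txt"))
    manifest <- list(
      analysis = "prediction",
      model = list(markers = model$markers,
                   thresholds = as.list(model$thresholds),
                   class_cut = model$class_cut),
      n_patients = nrow(scores),
      accuracy = if (!is.null(evaluation)) evaluation$accuracy
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(relative_expression = rel, scores = scores, evaluation = evaluation)
}
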