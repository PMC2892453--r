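# The predictive score: per-marker integer thresholds set just above the
# 98th percentile of the responder (CR) expression distribution, binary
# scoring, summation and the class cut (sum >= 2 of 3 predicts refractory).

#' Calibrate the percentile-threshold score model
#'
#' For every marker, computes the 98th percentile of the CR-group relative
#' expressions (linear-interpolation percentile, quantile type 7) and sets
#' the threshold to the first integer strictly above it,
#' `floor(p98) + 1`. The integer-ceiling step makes the rule robust to the
#' exact percentile dialect.
#'
#' @param cr_expressions Data frame or matrix of CR-patient relative
#'   expressions, one column per marker (>= 2 values each, positive).
#' @param class_cut Score at or above which a patient is called NR
#'   (default 2, the 0-1 vs 2-3 rule of the three-marker panel).
#' @return Object of class `score_model`: list with `markers`, named integer
#'   `thresholds` and `class_cut`.
#' @export
calibrate_score <- function(cr_expressions, class_cut = 2) {
  x <- as.data.frame(cr_expressions, stringsAsFactors = FALSE)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  if (!ncol(x)) fl_stop("no numeric marker columns in `cr_expressions`",
                        "flumir_parameter_error")
  if (nrow(x) < 2L) {
    fl_stop("need at least 2 CR values per marker", "flumir_parameter_error")
  }
  if (any(vapply(x, function(v) anyNA(v) || any(v <= 0), TRUE))) {
    fl_stop("CR expressions must be positive and complete", "flumir_parameter_error")
  }
  p98 <- vapply(x, function(v) stats::quantile(v, 0.98, type = 7, names = FALSE), 0)
  thresholds <- as.integer(floor(p98)) + 1L
  markers <- colnames(x)
  if (!is_count(class_cut) || class_cut < 1 || class_cut > length(markers)) {
    fl_stop(sprintf("`class_cut` must be in 1..%d", length(markers)),
            "flumir_parameter_error")
  }
  structure(list(markers = markers,
                 thresholds = stats::setNames(thresholds, markers),
                 class_cut = as.integer(class_cut)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model>\n")
  for (m in x$markers) cat(sprintf("  %s >= %d\n", m, x$thresholds[[m]]))
  cat(sprintf("  predict NR when score >= %d (of %d)\n", x$class_cut,
              length(x$markers)))
  invisible(x)
}

#' Score patients against a calibrated model
#'
#' Each marker contributes 1 when the patient's expression reaches its
#' threshold (the at-threshold case scores 1; thresholds are integers
#' strictly above the CR 98th percentile, so equality is a boundary
#' convention, not a common event) and 0 otherwise. The total score drives
#' the class call: NR when `total >= class_cut`, else CR.
#'
#' @param model A [calibrate_score()] model.
#' @param expressions Data frame or matrix of relative expressions with one
#'   column per model marker; an optional `patient_id` column (or rownames)
#'   labels the output.
#' @return Data frame with `patient_id`, one 0/1 column per marker,
#'   `total_score` and `predicted_class`.
#' @export
score_patients <- function(model, expressions) {
  if (!inherits(model, "score_model")) fl_stop("`model` must be a score_model")
  x <- as.data.frame(expressions, stringsAsFactors = FALSE)
  miss <- setdiff(model$markers, colnames(x))
  if (length(miss)) {
    fl_stop(sprintf("marker value(s) missing: %s", paste(miss, collapse = ", ")),
            "flumir_data_error")
  }
  if (!nrow(x)) fl_stop("no patients to score", "flumir_parameter_error")
  vals <- x[model$markers]
  if (any(vapply(vals, anyNA, TRUE))) {
    fl_stop("missing expression values", "flumir_data_error")
  }
  pid <- x$patient_id %||%
    (if (!is.null(rownames(expressions)) &&
         !identical(rownames(expressions), as.character(seq_len(nrow(x)))))
      rownames(expressions) else sprintf("patient-%02d", seq_len(nrow(x))))
  scores <- vapply(model$markers,
                   function(m) as.integer(vals[[m]] >= model$thresholds[[m]]),
                   integer(nrow(x)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = nrow(x))
  colnames(scores) <- model$markers
  total <- rowSums(scores)
  out <- data.frame(patient_id = pid, scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$total_score <- as.integer(total)
  out$predicted_class <- ifelse(total >= model$class_cut, "NR", "CR")
  rownames(out) <- NULL
  out
}

#' Evaluate score predictions against true classes
#'
#' @param model A [calibrate_score()] model.
#' @param expressions Per-patient marker expressions (see
#'   [score_patients()]).
#' @param truth Character vector of true classes (`CR`/`NR`) aligned with
#'   the rows of `expressions`, or named by patient id.
#' @return Object of class `score_evaluation`: list with per-patient
#'   `predictions` (including the truth column), the 2x2 `confusion` table,
#'   `accuracy` and `misclassified` patient ids.
#' @export
evaluate_score <- function(model, expressions, truth) {
  pred <- score_patients(model, expressions)
  if (!is.null(names(truth))) truth <- truth[pred$patient_id]
  truth <- as.character(truth)
  if (length(truth) != nrow(pred) || anyNA(truth)) {
    fl_stop("`truth` must provide a CR/NR label for every patient",
            "flumir_parameter_error")
  }
  if (!all(truth %in% RESPONSES)) {
    fl_stop("`truth` labels must be CR or NR", "flumir_parameter_error")
  }
  pred$true_class <- truth
  confusion <- table(truth = factor(truth, RESPONSES),
                     predicted = factor(pred$predicted_class, RESPONSES))
  structure(list(
    predictions = pred, confusion = confusion,
    accuracy = mean(pred$predicted_class == truth),
    misclassified = pred$patient_id[pred$predicted_class != truth]
  ), class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("<score_evaluation> accuracy %.1f%% on %d patients\n",
              100 * x$accuracy, nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

#' Write a score model to a plain-text file
#'
#' One `marker<TAB>threshold` line per marker plus a final
#' `class_cut<TAB>value` line; integers round-trip exactly through
#' [read_score_model()].
#'
#' @param model A `score_model`.
#' @param path Destination path.
#' @export
write_score_model <- function(model, path) {
  if (!inherits(model, "score_model")) fl_stop("`model` must be a score_model")
  writeLines(c(sprintf("%s\t%d", model$markers, model$thresholds),
               sprintf("class_cut\t%d", model$class_cut)), path)
  invisible(path)
}

#' Read a score model written by [write_score_model()]
#'
#' @param path Path to the model file.
#' @export
read_score_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L) || length(parts) < 2L ||
      parts[[length(parts)]][1L] != "class_cut") {
    fl_stop("malformed score model file", "flumir_format_error")
  }
  n <- length(parts) - 1L
  markers <- vapply(parts[seq_len(n)], `[[`, "", 1L)
  thresholds <- as.integer(vapply(parts[seq_len(n)], `[[`, "", 2L))
  cut <- as.integer(parts[[n + 1L]][2L])
  if (anyNA(thresholds) || is.na(cut)) {
    fl_stop("non-integer threshold in score model file", "flumir_format_error")
  }
  structure(list(markers = markers,
                 thresholds = stats::setNames(thresholds, markers),
                 class_cut = cut),
            class = "score_model")
}
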