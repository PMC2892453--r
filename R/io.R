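EXPR_SCALES <- c("raw-linear", "normalized-linear", "log2")
TIMEPOINTS <- c("pre", "post")
RESPONSES <- c("CR", "NR")
COHORTS <- c("training", "test")

#' Expression matrix with presence flags
#'
#' Container for a features-by-samples intensity matrix together with a
#' per-cell presence flag and a scale tag. All analysis functions in the
#' package operate on this class; files are only touched by the readers and
#' writers.
#'
#' @param values Numeric matrix, features in rows (rownames are feature ids),
#'   samples in columns (colnames are sample ids). Ids must be unique.
#' @param flags Logical matrix of the same shape: `TRUE` where the feature was
#'   called present in that sample. `NULL` means all cells present.
#' @param scale One of `"raw-linear"`, `"normalized-linear"`, `"log2"`.
#'   Log2-scale matrices must contain only finite values.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `flags` and `scale`.
#' @export
expression_matrix <- function(values, flags = NULL,
                              scale = c("raw-linear", "normalized-linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    fl_stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fl_stop("`values` must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    fl_stop(sprintf("duplicated feature id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    fl_stop(sprintf("duplicated sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(values)) fl_stop("`values` must not contain missing cells")
  if (is.null(flags)) {
    flags <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!is.matrix(flags) || !is.logical(flags) ||
      !identical(dim(flags), dim(values))) {
    fl_stop(sprintf(
      "flag matrix shape (%s) does not match value matrix shape (%s)",
      paste(dim(flags), collapse = " x "), paste(dim(values), collapse = " x ")
    ))
  }
  dimnames(flags) <- dimnames(values)
  if (scale == "log2" && !all(is.finite(values))) {
    fl_stop("log2-scale matrices must contain only finite values",
            class = "flumir_state_error")
  }
  structure(list(values = values, flags = flags, scale = scale),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
`[.expr_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE], x$flags[i, j, drop = FALSE],
                    x$scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, scale = %s, %.1f%% present\n",
              nrow(x$values), ncol(x$values), x$scale, 100 * mean(x$flags)))
  invisible(x)
}

#' Read a tab-separated expression matrix (with optional flag matrix)
#'
#' Expects a header row of sample ids and a first column of feature ids; all
#' remaining cells numeric. The optional flag file has the identical layout
#' with cells coded `P` (present) or `A` (absent).
#'
#' @param path Path to the value table.
#' @param flag_path Optional path to the flag table. When omitted, every cell
#'   is treated as present.
#' @return An [expression_matrix()] with `scale = "raw-linear"`.
#' @export
read_expression_matrix <- function(path, flag_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) fl_stop("expression file needs a feature-id column plus at least one sample column")
  feature_ids <- raw[[1L]]
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(feature_ids, colnames(raw)[-1L]))
  for (j in seq(2L, ncol(raw))) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad)) {
      fl_stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                      raw[[j]][bad[1L]], feature_ids[bad[1L]], colnames(raw)[j]))
    }
    if (anyNA(num)) {
      fl_stop(sprintf("missing value at feature '%s', sample '%s'",
                      feature_ids[which(is.na(num))[1L]], colnames(raw)[j]))
    }
    vals[, j - 1L] <- num
  }
  flags <- if (!is.null(flag_path)) read_flag_matrix(flag_path) else NULL
  if (!is.null(flags) && !identical(dim(flags), dim(vals))) {
    fl_stop(sprintf(
      "flag table shape (%s) does not match value table shape (%s)",
      paste(dim(flags), collapse = " x "), paste(dim(vals), collapse = " x ")
    ))
  }
  if (!is.null(flags) && !identical(dimnames(flags), dimnames(vals))) {
    fl_stop("flag table ids do not match value table ids")
  }
  expression_matrix(vals, flags, scale = "raw-linear")
}

# Flag files use the closed vocabulary P/A; anything else is rejected.
read_flag_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- !(m %in% c("P", "A"))
  if (any(bad)) {
    fl_stop(sprintf("flag code '%s' is not one of P/A", m[which(bad)[1L]]))
  }
  out <- m == "P"
  rownames(out) <- ids
  out
}

#' Write an expression matrix (and optionally its flags) to tab-separated files
#'
#' @param m An [expression_matrix()].
#' @param path Destination for the value table.
#' @param flag_path Optional destination for the P/A flag table.
#' @export
write_expression_matrix <- function(m, path, flag_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(flag_path)) {
    fl <- ifelse(m$flags, "P", "A")
    df2 <- data.frame(feature_id = rownames(m$values), fl,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df2, flag_path)
  }
  invisible(path)
}

#' Sample metadata table
#'
#' Validates a data frame of per-sample metadata. Each row describes one
#' hybridized sample: its patient, the timepoint relative to the fludarabine
#' course (`pre` = one day before, `post` = day 5), the patient's clinical
#' response class (`CR` responder, `NR` refractory) and the cohort
#' (`training` or `test`). Test-cohort samples are pre-treatment only, and a
#' patient contributes at most one sample per timepoint within a cohort.
#'
#' @param df A data frame with columns `sample_id`, `patient_id`, `timepoint`,
#'   `response`, `cohort`.
#' @return The validated data frame with class `sample_info`.
#' @export
as_sample_info <- function(df) {
  required <- c("sample_id", "patient_id", "timepoint", "response", "cohort")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    fl_stop(sprintf("sample sheet lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cl in required) {
    df[[cl]] <- as.character(df[[cl]])
    if (anyNA(df[[cl]]) && nrow(df)) fl_stop(sprintf("missing values in column '%s'", cl))
  }
  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad)) {
      fl_stop(sprintf("unknown %s code(s): %s (allowed: %s)", col,
                      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
    }
  }
  check_enum("timepoint", TIMEPOINTS)
  check_enum("response", RESPONSES)
  check_enum("cohort", COHORTS)
  if (anyDuplicated(df$sample_id)) {
    fl_stop(sprintf("duplicated sample id(s): %s",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  key <- paste(df$patient_id, df$timepoint, df$cohort, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    fl_stop(sprintf("more than one sample for patient '%s' at timepoint '%s' in the %s cohort",
                    dup$patient_id[1L], dup$timepoint[1L], dup$cohort[1L]))
  }
  bad <- df$cohort == "test" & df$timepoint == "post"
  if (any(bad)) {
    fl_stop(sprintf("test-cohort samples must be pre-treatment (offending sample '%s')",
                    df$sample_id[which(bad)[1L]]))
  }
  class(df) <- c("sample_info", "data.frame")
  df
}

#' Read a tab-separated sample sheet
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `patient_id`, `timepoint` (pre/post), `response` (CR/NR) and `cohort`
#'   (training/test).
#' @return A validated `sample_info` data frame (possibly with zero rows).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  as_sample_info(df)
}

#' Gene-set collection
#'
#' @param sets Named list of character vectors of member ids. Sets must be
#'   non-empty and names unique; duplicate members within a set are dropped.
#' @param universe Optional character vector giving the background universe.
#' @return Object of class `gene_sets`.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    fl_stop("`sets` must be a named list of member-id vectors")
  }
  if (anyDuplicated(names(sets))) {
    fl_stop(sprintf("duplicated set name(s): %s",
                    paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) {
    fl_stop(sprintf("empty gene set(s): %s",
                    paste(names(sets)[lengths(sets) == 0L], collapse = ", ")))
  }
  structure(sets, universe = universe, class = "gene_sets")
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, tab-separated fields
#' `name`, `description`, then one or more member ids.
#'
#' @param path Path to the GMT file.
#' @return A [gene_sets()] collection keyed by set name.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    fl_stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                    short[1L], lengths(fields)[short[1L]]),
            class = "flumir_format_error")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_sets(sets)
}

#' qPCR Ct table
#'
#' Long-format table of raw threshold-cycle measurements: one row per
#' (sample, target, replicate). The reference target (the endogenous control,
#' e.g. RNU6B/U6) must be measured in every sample so that delta-Ct values can
#' be formed.
#'
#' @param df Data frame with columns `sample_id`, `target_id`, `replicate`,
#'   `ct` (positive, finite PCR cycle numbers).
#' @param reference_target Id of the reference (normalizer) target.
#' @return The validated data frame with class `ct_table` and attribute
#'   `reference_target`.
#' @export
ct_table <- function(df, reference_target) {
  required <- c("sample_id", "target_id", "replicate", "ct")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    fl_stop(sprintf("Ct table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$ct <- as.numeric(df$ct)
  if (!all(is.finite(df$ct)) || any(df$ct <= 0)) {
    fl_stop("Ct values must be positive and finite")
  }
  if (!is.character(reference_target) || length(reference_target) != 1L) {
    fl_stop("`reference_target` must be a single target id")
  }
  samples <- unique(df$sample_id)
  has_ref <- samples %in% df$sample_id[df$target_id == reference_target]
  if (!all(has_ref)) {
    fl_stop(sprintf("reference target '%s' missing for sample(s): %s",
                    reference_target, paste(samples[!has_ref], collapse = ", ")),
            class = "flumir_data_error")
  }
  structure(df, reference_target = reference_target,
            class = c("ct_table", "data.frame"))
}

#' Read a tab-separated Ct table
#'
#' @inheritParams ct_table
#' @param path Path to a tab-separated file with the [ct_table()] columns.
#' @export
read_ct_table <- function(path, reference_target) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ct_table(df, reference_target)
}

#' Write a results table to a tab-separated file
#'
#' Numeric columns are rounded to `digits` significant digits; the file
#' round-trips through [read_results_table()] up to that precision.
#'
#' @param records A data frame of results (may have zero rows).
#' @param path Destination path.
#' @param digits Significant digits for numeric columns (default 4).
#' @export
write_results_table <- function(records, path, digits = 4) {
  if (!is.data.frame(records)) fl_stop("`records` must be a data frame")
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  write_tsv(out, path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the file.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    fl_stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
            class = "flumir_io_error")
  }
  invisible(path)
}
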