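# In-code fixtures; nothing is read from disk except through temp files the
# tests themselves write.

make_em <- function(values, flags = NULL, scale = "raw-linear",
                    feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  rownames(values) <- feature_ids %||% sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- sample_ids %||% sprintf("s%02d", seq_len(ncol(values)))
  if (!is.null(flags)) dimnames(flags) <- dimnames(values)
  expression_matrix(values, flags, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A noiseless training design: planted effects only, no negatives, no absent
# flags, so downstream recovery is exact.
noiseless_design <- function(...) {
  cohort_design(noise_log2_sd = 0, negative_rate = 0, flag_absent_rate = 0,
                baseline_log2_sd = 1, ...)
}
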