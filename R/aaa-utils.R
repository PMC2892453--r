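# Classed conditions: every user-facing failure carries a class so callers can
# distinguish validation problems from state/parameter misuse programmatically.
fl_stop <- function(msg, class = "flumir_validation_error") {
  stop(structure(
    class = c(class, "flumir_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
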