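# Condition helpers. Every package error carries a subclass so callers can
# distinguish e.g. an unknown database label from an empty denominator.

sr_abort <- function(class, message, ...) {
  abort(message, class = c(paste0("searchrecall_", class), "searchrecall_error"), ...)
}

check_positive_denominator <- function(x, what, class = "empty_denominator") {
  if (any(!is.finite(x)) || any(x <= 0)) {
    sr_abort(class, sprintf("%s must be positive (got %s); the measure is undefined.",
                            what, paste(x[x <= 0 | !is.finite(x)], collapse = ", ")))
  }
  invisible(x)
}
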