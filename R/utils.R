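# Internal input checkers shared by the scoring functions.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid input `%s`: %s", field, msg), call. = FALSE)
}

stop_missing <- function(components) {
  stop(sprintf("missing required component(s): %s",
               paste(components, collapse = ", ")), call. = FALSE)
}

# Vectorised positivity check; NA counts as missing.
check_positive <- function(x, field) {
  if (length(x) == 0) stop_invalid(field, "empty")
  if (anyNA(x)) stop_invalid(field, "missing value (NA)")
  if (!is.numeric(x)) stop_invalid(field, "not numeric")
  if (any(x <= 0)) stop_invalid(field, "must be strictly positive")
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (length(x) == 0) stop_invalid(field, "empty")
  if (anyNA(x)) stop_invalid(field, "missing value (NA)")
  if (!is.numeric(x)) stop_invalid(field, "not numeric")
  if (any(x < 0)) stop_invalid(field, "must be non-negative")
  invisible(x)
}

check_prob <- function(x, field) {
  if (anyNA(x) || !is.numeric(x) || any(x < 0 | x > 1)) {
    stop_invalid(field, "must be a proportion in [0, 1]")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
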