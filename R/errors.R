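# Classed conditions so callers (and the CLI wrapper) can distinguish
# validation, format, I/O and configuration failures.

abort_validation <- function(msg, class = NULL, ...) {
  rlang::abort(msg, class = c(class, "swimprot_validation_error"), ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "swimprot_format_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "swimprot_io_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "swimprot_config_error", ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    abort_validation(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort_validation(sprintf("`%s` must be >= %s", name, format(min)))
  }
  if (x > max) {
    abort_validation(sprintf("`%s` must be <= %s", name, format(max)))
  }
  invisible(x)
}
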