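## Classed error conditions so callers can distinguish bad inputs from
## numerical failures programmatically.

stop_memmech <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "memmech_error")))
}

stop_invalid_input <- function(msg, ...) {
  stop_memmech(msg, "memmech_invalid_input", ...)
}

stop_fit_failure <- function(msg, ...) {
  stop_memmech(msg, "memmech_fit_failure", ...)
}

stop_not_found <- function(msg, ...) {
  stop_memmech(msg, "memmech_not_found", ...)
}

stop_undefined_cmc <- function(msg, ...) {
  stop_memmech(msg, "memmech_undefined_cmc", ...)
}

stop_out_of_range <- function(msg, ...) {
  stop_memmech(msg, "memmech_out_of_range", ...)
}

stop_invalid_spec <- function(msg, ...) {
  stop_memmech(msg, "memmech_invalid_spec", ...)
}

## scalar numeric check used throughout
check_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid_input(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) {
    stop_invalid_input(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    stop_invalid_input(sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}
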