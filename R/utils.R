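# Error helpers. Three classes drive the CLI exit codes:
#   survcloak_error_validation  -> exit 2
#   survcloak_error_disclosure  -> exit 3
#   survcloak_error_config      -> exit 2
stop_validation <- function(msg, ...) {
  abort(msg, class = "survcloak_error_validation", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "survcloak_error_config", ...)
}

stop_disclosure <- function(msg, ...) {
  abort(msg, class = "survcloak_error_disclosure", ...)
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG state;
# with seed = NULL the global stream is used as-is.
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop_validation("`seed` must be a single finite number.")
    }
    withr::with_seed(as.integer(seed), expr)
  }
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_validation(sprintf(
      "`%s` must be a single finite number in [%s, %s].", name,
      format(min), format(max)
    ))
  }
  as.numeric(x)
}
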