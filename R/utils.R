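# Internal helpers shared across modules.

# Consistent error for bad configuration values; `field` names the offender.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

stop_dimension <- function(msg) {
  stop(sprintf("dimension error: %s", msg), call. = FALSE)
}

# All stochastic entry points funnel through this: the caller's RNG state is
# untouched and the same seed always yields the same stream.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    config_error("seed", "must be a single finite number")
  }
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
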