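# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("slidewise_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("slidewise_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop_input(name, " must be a finite number in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

# All stochastic entry points funnel their randomness through this: the
# caller's RNG state is untouched and an explicit seed fully determines
# the output.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed so one user-facing seed can drive
# several independent generators without coupling their draws.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 1009L) %% 2147483562L
}
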