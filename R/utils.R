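# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

# deterministic per-stream sub-seed so adding a generator never perturbs
# the draws of another; kept below 2^31 (R integers are 32-bit)
derive_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop_domain("'seed' must be a single nonnegative integer")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
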