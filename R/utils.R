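# internal helpers shared across modules

# Run `code` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; otherwise run on the current stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive `k` child seeds (< 2^31) from the current RNG stream.
child_seeds <- function(k) {
  sample.int(.Machine$integer.max - 1L, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
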