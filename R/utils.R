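# Internal helpers shared across modules.

# Derive a child seed from a global seed and a stage label, deterministically
# and within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, preprocess = 211L, select = 307L, wrapper = 401L,
    eliminate = 503L, split = 601L, train = 701L, evaluate = 811L,
    internal_split = 907L
  )
  off <- offsets[stage]
  if (is.na(off)) off <- abs(sum(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Run code under a temporary RNG seed without disturbing the caller's RNG
# stream; seed = NULL runs unseeded.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)),
          class = "graftann_config_error")
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
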