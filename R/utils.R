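# Internal helpers: seeded RNG scoping and named sub-streams.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  force(code)
}

# Deterministic sub-seed for a named stage, kept inside 32-bit integer range
# so the same master seed can drive independent generator stages.
stream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) %% 2000003 * 1009 + h * 97 + 17) %% 2147483629)
}

# Tiny FNV-1a style hash of a character scalar, for config fingerprints in
# file headers (not cryptographic).
config_hash <- function(x) {
  x <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
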