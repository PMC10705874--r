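# Internal helpers shared across modules.

# Deterministic seed derivation: mixes a base seed with grid coordinates by
# polynomial hashing modulo a Mersenne prime, so every experiment cell gets a
# reproducible stream independent of evaluation order or worker count.
# All arithmetic stays below 2^53, exact in doubles; result is in [1, 2^31-2].
derive_seed <- function(base_seed, ...) {
  parts <- list(base_seed, ...)
  m <- 2147483647
  h <- 17
  for (p in parts) {
    stopifnot(is.numeric(p) || is.character(p))
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% m
    }
    h <- (h * 31 + (as.numeric(p) %% m)) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# round-half-up, used for injected feature counts (round() in R rounds half
# to even, which would make e.g. 10% of 265 depend on IEEE representation)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run an expression under a local RNG state so package internals never
# perturb the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
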