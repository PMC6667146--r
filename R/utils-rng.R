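## Seed discipline: every stochastic operation draws from a locally scoped RNG
## so that package functions never disturb the caller's .Random.seed and are
## reproducible from an explicit integer seed.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's random-number state around `expr`, so the
#' expression sees a reproducible stream seeded by `seed`.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a stream label. Keeps results
## below 2^31 so they remain valid R integers.
mix_seed <- function(seed, label) {
  h <- hash_string(paste0("s", seed, "/", label))
  as.integer(h %% 2147483629) + 1L
}

## Deterministic 31-bit polynomial string hash (double arithmetic keeps every
## intermediate exact below 2^53).
hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 5381
  for (c in codes) h <- (h * 33 + c) %% 2147483647
  h
}

## Deterministic pseudo-random uniform(-a, a) vector keyed by an arbitrary
## string and a seed; used for out-of-vocabulary embeddings. A multiplicative
## Lehmer generator on the hashed key gives reproducibility without touching
## R's global RNG.
keyed_uniform <- function(key, seed, n, a) {
  state <- (hash_string(paste0(key, "#", seed)) %% 2147483398) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 40692) %% 2147483399
    out[i] <- state / 2147483399
  }
  (out * 2 - 1) * a
}
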