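# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seeds: every source of randomness in a multi-stage run
# flows from one user seed. Constants are primes; result stays < 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729 + 13) %% 2147483629)
}

# sample fold labels 1..k of near-equal size for n observations
foldAssignment <- function(n, k, seed) {
  if (k < 2 || k > n) stop("fold count k must satisfy 2 <= k <= n")
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
}
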