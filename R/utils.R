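## Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never
# perturb user-level random streams.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic fan-out of one master seed into n child seeds (< 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}

stopUnlessScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%g, %g]",
                 name, lower, upper), call. = FALSE)
  }
  invisible(x)
}
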