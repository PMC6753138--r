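## Internal RNG helpers. All stochastic steps take an explicit integer seed
## and restore the caller's RNG state, so that pipeline results are
## reproducible and independent of the surrounding session.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Uniform(0,1) generator bound to its own stream
seededRng <- function(seed) {
  env <- new.env()
  env$state <- withSeed(seed, {
    stats::runif(1)
    get(".Random.seed", envir = globalenv())
  })
  function() {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(1)
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

## Derive a child seed from a master seed; kept below 2^31.
deriveSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

## Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column
## integer matrix, column-major order matching which(upper.tri(.)).
upperPairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)))
  j <- ((idx - 1L) %/% n) + 1L
  i <- idx - (j - 1L) * n
  cbind(i = i, j = j)
}
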