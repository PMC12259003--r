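# Small internal helpers.

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# A self-contained RNG stream seeded once; each draw resumes the stream and
# leaves the caller's global RNG untouched.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f, ...) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    res <- f(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd),
    sample_int = function(n, size = 1L, replace = FALSE)
      run(sample.int, n, size, replace)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
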