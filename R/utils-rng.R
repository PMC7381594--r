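# Seeded RNG stream isolated from the global random state, so that every
# randomized procedure is reproducible from its own seed argument and never
# perturbs (or is perturbed by) the caller's RNG.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    f()
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      run(function() sample.int(n, size = size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      run(function() stats::rnorm(n, mean, sd)),
    eval = function(f) run(f)
  )
}

# evaluate f() under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, f) local_rng(seed)$eval(f)
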