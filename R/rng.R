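# Seeded random-number scope, isolated from the caller's RNG state.
# Every stochastic operation in the package draws through one of these,
# so results are reproducible given a seed and never perturb (or depend
# on) the global random stream.

.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  local({
    old <- .GlobalEnv$.Random.seed
    set.seed(as.integer(seed))
    env$state <- .GlobalEnv$.Random.seed
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  run <- function(f) {
    old <- .GlobalEnv$.Random.seed
    assign(".Random.seed", env$state, envir = .GlobalEnv)
    on.exit({
      env$state <- .GlobalEnv$.Random.seed
      if (is.null(old)) {
        if (!is.null(.GlobalEnv$.Random.seed)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    })
    f()
  }
  list(
    # safe even when x has length 1: samples from x itself, never 1:x
    sample = function(x, size, replace = FALSE, prob = NULL) {
      run(function() x[sample.int(length(x), size, replace = replace,
                                  prob = prob)])
    },
    sample_int = function(n, size, replace = FALSE, prob = NULL) {
      run(function() sample.int(n, size, replace = replace, prob = prob))
    },
    runif = function(n, min = 0, max = 1) {
      run(function() stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      run(function() stats::rnorm(n, mean, sd))
    },
    run = run
  )
}
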