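# Internal utilities.

# A private RNG stream: every draw saves and restores the caller's
# .Random.seed, so library code never perturbs user-visible randomness.
# All stochastic components of the package draw through one of these.
make_rng <- function(seed) {
  seed <- as.integer(seed)
  state <- local({
    old <- get_global_seed()
    set.seed(seed, kind = "Mersenne-Twister")
    s <- .Random.seed
    restore_global_seed(old)
    s
  })
  draw <- function(fn) {
    old <- get_global_seed()
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      restore_global_seed(old)
    })
    fn()
  }
  list(
    runif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    sample = function(n, size = n, replace = FALSE, prob = NULL)
      draw(function() sample.int(n, size, replace = replace, prob = prob)),
    rint = function(n, lo, hi)
      draw(function() lo + floor(stats::runif(n) * (hi - lo + 1L)))
  )
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_odd <- function(k) (k %% 2L) == 1L

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}
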