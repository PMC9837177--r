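#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, runs `code`, and restores the caller's random stream,
#' so seeded package operations never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  code
}

# A resumable seeded RNG stream independent of the global one.
# Returns closures over the usual samplers; each call continues the stream.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  env$seed0 <- as.integer(seed)
  run <- function(f) function(...) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(env$state)) set.seed(env$seed0)
    else assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    f(...)
  }
  list(runif = run(stats::runif), rnorm = run(stats::rnorm),
       sample = run(base::sample), rbinom = run(stats::rbinom),
       rpois = run(stats::rpois), rexp = run(stats::rexp))
}

# L2 norm
l2 <- function(x) sqrt(sum(x^2))

#' Normalize a vector to unit L2 norm
#' @param x numeric vector.
#' @param tol vectors with norm below this are an error.
#' @return `x / ||x||`.
#' @export
unitize <- function(x, tol = 1e-12) {
  n <- l2(x)
  if (!is.finite(n) || n < tol) stop("cannot normalize a zero-norm vector")
  x / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
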