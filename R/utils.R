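#' @importFrom stats runif rlnorm optim ks.test dgamma dweibull setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `expr`, and
#' restores the previous state on exit, so seeded package operations never
#' disturb the caller's random number stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## parts-per-million mass window around a reference mass
ppmWindow <- function(mass, ppm) mass * ppm * 1e-6

## TRUE where |a - b| is within max(ppm of ref, abs Da); the permissive
## combination used throughout for peak/node matching
massMatches <- function(a, b, ppm = 10, absDa = 0.002) {
  abs(a - b) <= pmax(abs(b) * ppm * 1e-6, absDa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stable 32-bit sub-seed derived from a master seed and a stream index
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}
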