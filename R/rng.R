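#' Derive a child seed from a root seed
#'
#' All stochastic components of the package draw their randomness from one
#' root seed; independent streams (per element, per slice, per experiment
#' stage) use child seeds derived by counter-based splitting so that runs
#' are reproducible and sub-computations are order-independent.
#'
#' @param seed integer root seed.
#' @param ... one or more integer counters identifying the stream.
#' @return a single integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
split_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    # multiplicative mixing, all arithmetic exact in doubles (< 2^53)
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so calling code's random stream is
#' not disturbed.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
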