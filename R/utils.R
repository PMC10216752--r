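#' Evaluate an expression with a private RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper: the global `.Random.seed` is saved, the given seed installed,
#' and the previous state restored afterwards, so no generator leaks RNG
#' state into the caller's session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific child seed from a base seed; stays < 2^31
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647
}

stop_if_not_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

# trapezoidal quadrature
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
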