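# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation so independent stochastic stages can be
# seeded from one master seed without sharing a stream.  Kept below 2^31-1.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, ...) {
  keys <- list(...)   # a list, so numeric keys are not coerced to strings
  h <- as.double(seed) %% 2147483629
  for (k in keys) {
    kv <- if (is.character(k)) {
      u <- utf8ToInt(k)
      sum(u * seq_along(u))
    } else as.double(k)
    h <- (h * 48271 + kv + 1) %% 2147483629
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG state, restoring the caller's state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Trapezoidal integration on an arbitrary increasing grid.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Circular shift of a vector by `offset` (positive shifts forward in time:
# element t of the result is element t - offset of the input, wrapped).
#' @keywords internal
#' @noRd
circular_shift <- function(x, offset) {
  n <- length(x)
  offset <- offset %% n
  if (offset == 0L) return(x)
  c(x[(n - offset + 1L):n], x[1L:(n - offset)])
}

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
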