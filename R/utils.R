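#' @keywords internal
"_PACKAGE"

#' Evaluate code under a private RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `code`, and restores the caller's RNG state on exit. All
#' stochastic functions in the package route their randomness through this so
#' that (inputs, seed) -> output is a pure function and library calls never
#' disturb the user's session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# clamp numeric vector
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
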