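# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message (no call in the condition)
#' @noRd
abort <- function(...) stop(sprintf(...), call. = FALSE)

#' Check a condition, abort with message otherwise
#' @noRd
check_that <- function(cond, ...) if (!isTRUE(cond)) abort(...)

#' Evaluate an expression under a local RNG seed, restoring the caller's RNG
#' @noRd
with_rng <- function(seed, expr) {
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
  expr
}

#' Derive a child seed from a base seed and a stream index, < 2^31
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629L) + 1L
}
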