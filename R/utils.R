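# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
softmax <- function(x) {
  x <- x - max(x)                       # shift for overflow safety
  e <- exp(x)
  e / sum(e)
}

#' Run an expression under a fixed RNG state, restoring the caller's state.
#'
#' Every generator in the package routes its randomness through this helper,
#' so equal seeds give bitwise-equal output and no call leaks RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' @keywords internal
#' @noRd
l2_normalize_rows <- function(x, eps = 1e-12) {
  n <- sqrt(rowSums(x^2))
  x / pmax(n, eps)
}

#' @keywords internal
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
#' @noRd
assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
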