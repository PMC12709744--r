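# Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package take an explicit seed and leave
#' the caller's RNG stream untouched.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  code
}

# Stop with a consistent error class so callers/tests can condition on it.
stop_stabsize <- function(msg, class) {
  stop(structure(
    class = c(class, "stabsize_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Coerce a predictor row (or matrix) to a design row(s) with leading intercept.
design_with_intercept <- function(x) {
  x <- as.matrix(x)
  cbind(`(intercept)` = 1, x)
}

# Four-number summary used throughout the instability tables.
four_num <- function(x) {
  c(mean = mean(x), min = min(x), median = stats::median(x), max = max(x))
}
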