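#' Fisher's unit information matrix for the exponential core model
#'
#' Decomposes the information about the (P+1) model parameters into the
#' sample size and a per-participant *unit* information matrix
#' \deqn{I = E\left( x_i' x_i \, w_i \right), \qquad w_i = \exp(y_i +
#'   \hat\mu_i) = t_i \exp(\hat\mu_i),}
#' where \eqn{x_i = (1, x_{1i}, \dots, x_{Pi})} is the design row,
#' \eqn{y_i} the observed log follow-up time (minimum of log event and log
#' censoring time) and \eqn{\hat\mu_i} the linear predictor under the core
#' model held at its anticipated true parameter values. The expectation is
#' estimated by the sample mean over the supplied cohort. Then
#' \eqn{\mathrm{var}(\hat\beta) = n^{-1} I^{-1}} for a development sample of
#' size n.
#'
#' @param cohort A [cohort()] with follow-up (observed or simulated).
#' @param model A [core_model()] scoring the cohort; its parameters define
#'   \eqn{\hat\mu_i}.
#' @param mu Optional vector overriding the model-based \eqn{\hat\mu_i}
#'   (e.g. fitted values for post-fit analyses).
#' @return A `unit_information` with elements `matrix`, `inverse`,
#'   `weights`, `n_source`, `condition`.
#' @export
#' @examples
#' ch <- cohort(cbind(z = c(0, 0, 0)), time = c(1, 2, 0.5), event = c(1, 1, 1))
#' m <- core_model(alpha = 0, weights = c(z = 1), delta = 0, horizon = 5)
#' unit_information(ch, m)$matrix
unit_information <- function(cohort, model, mu = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$time)) {
    stop_stabsize("cohort has no follow-up; simulate or observe times first",
                  "state_error")
  }
  if (is.null(mu)) {
    stopifnot(inherits(model, "core_model"))
    mu <- linear_predictor(model, cohort)$mu
  }
  X <- design_with_intercept(model_design(cohort, model))
  n <- nrow(X)
  if (n < ncol(X)) {
    stop_stabsize("need at least as many individuals as parameters",
                  "state_error")
  }
  w <- cohort$time * exp(mu)
  I <- crossprod(X, X * w) / n
  I <- (I + t(I)) / 2  # enforce exact symmetry
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_stabsize(sprintf("singular information: collinear column(s) %s",
                          paste(bad, collapse = ", ")),
                  "singular_information_error")
  }
  cond <- kappa(I, exact = TRUE)
  if (!is.finite(cond) || cond > 1e10) {
    stop_stabsize(sprintf(
      "near-singular information matrix (condition number %.3g)", cond),
      "singular_information_error")
  }
  inv <- chol2inv(chol(I))
  dimnames(inv) <- dimnames(I)
  structure(list(matrix = I, inverse = inv, weights = w, n_source = n,
                 condition = cond),
            class = "unit_information")
}

# Predictor matrix in the model's column order (standardisation applied),
# or the raw predictors when no model is given.
model_design <- function(cohort, model = NULL) {
  if (is.null(model)) cohort$predictors else align_predictors(model, cohort)
}

#' @export
print.unit_information <- function(x, digits = 4, ...) {
  cat(sprintf("<unit information> %d x %d from %d individuals (condition %.3g)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_source, x$condition))
  print(round(x$matrix, digits))
  invisible(x)
}

#' @export
as.matrix.unit_information <- function(x, ...) x$matrix

#' Parameter covariance implied by a unit information matrix
#'
#' \eqn{\mathrm{var}(\hat\beta) = n^{-1} I^{-1}}: the anticipated
#' variance-covariance matrix of the model coefficients if the core model
#' were fitted to a development sample of size `n`.
#'
#' @param info A [unit_information()].
#' @param n Development sample size (> 0).
#' @return A (P+1) x (P+1) covariance matrix.
#' @export
parameter_covariance <- function(info, n) {
  stopifnot(inherits(info, "unit_information"), is.numeric(n), n > 0)
  info$inverse / n
}

#' Serialise a unit information matrix to JSON
#'
#' @param info A `unit_information`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_unit_information <- function(info, path) {
  stopifnot(inherits(info, "unit_information"))
  jsonlite::write_json(list(
    matrix = info$matrix, inverse = info$inverse,
    n_source = info$n_source, condition = info$condition,
    columns = colnames(info$matrix)
  ), path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
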