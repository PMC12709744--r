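#' Specify an exponential proportional-hazards core model
#'
#' The core model is the working model assumed true for design-stage
#' calculations: each individual has a constant event rate
#' \eqn{\eta_i = \exp(\mu_i)} with
#' \deqn{\mu_i = \alpha + \delta (\beta_1 x_{1i} + \dots + \beta_P x_{Pi})}
#' and event times exponentially distributed given \eqn{\eta_i}. The
#' intercept \eqn{\alpha} sets the baseline log rate per year, the weights
#' \eqn{\beta} carry the *relative* log-hazard-ratio effects and the
#' non-negative multiplier \eqn{\delta} their common scale (so only
#' \eqn{\delta \beta} is identified; calibration exploits this split).
#' Equivalently this is an accelerated failure time model,
#' \eqn{\ln t_i = -\mu_i + \varepsilon_i} with standard extreme-value noise.
#'
#' @param alpha Intercept (log baseline rate per year).
#' @param weights Named numeric vector of P relative weights, aligned to
#'   predictor columns of any cohort the model scores.
#' @param delta Non-negative multiplier on the weighted sum (default 1).
#' @param horizon Key prediction time-point t* in years.
#' @param standardisation Named list of `c(mean, sd)` pairs applied to
#'   predictor columns before scoring (usually inherited from the cohort the
#'   model was calibrated on).
#' @return An object of class `core_model`.
#' @seealso [calibrate()], [linear_predictor()], [event_risk()]
#' @export
#' @examples
#' m <- core_model(alpha = -2.3139, weights = c(z = 1), delta = 0, horizon = 5)
#' predict(m, cohort(cbind(z = c(-1, 0, 1))), type = "risk")
core_model <- function(alpha, weights, delta = 1, horizon = 5,
                       standardisation = list()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(delta), length(delta) == 1L, delta >= 0,
            is.numeric(horizon), length(horizon) == 1L, horizon > 0,
            is.numeric(weights))
  # length-0 weights give an intercept-only (null) model
  if (length(weights) > 0 &&
      (is.null(names(weights)) || anyDuplicated(names(weights)))) {
    stop_stabsize("weights must have unique names matching predictor columns",
                  "alignment_error")
  }
  structure(
    list(alpha = alpha, delta = delta, weights = weights, horizon = horizon,
         standardisation = standardisation),
    class = "core_model"
  )
}

#' @export
print.core_model <- function(x, digits = 4, ...) {
  cat(sprintf("<core model> exponential PH, horizon t* = %g years\n", x$horizon))
  cat(sprintf("  alpha = %.*f, delta = %.*f\n", digits, x$alpha, digits, x$delta))
  cat("  relative weights:\n")
  print(round(x$weights, digits))
  cal <- attr(x, "calibration")
  if (!is.null(cal)) {
    cat(sprintf("  calibrated (%s): C = %.4f, overall risk = %.4f (%d evaluations)\n",
                cal$method, cal$achieved_c, cal$achieved_risk, cal$iterations))
  }
  invisible(x)
}

#' @export
coef.core_model <- function(object, ...) {
  c("(intercept)" = object$alpha, object$delta * object$weights)
}

# Align a cohort's predictor matrix to the model's weights, applying the
# model's stored standardisation to any not-yet-standardised column.
align_predictors <- function(model, cohort) {
  X <- cohort$predictors
  if (length(model$weights) == 0L) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0))
  }
  missing_cols <- setdiff(names(model$weights), colnames(X))
  if (length(missing_cols)) {
    stop_stabsize(sprintf("cohort lacks predictor column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "alignment_error")
  }
  X <- X[, names(model$weights), drop = FALSE]
  for (cl in intersect(names(model$standardisation), colnames(X))) {
    if (is.null(cohort$standardisation[[cl]])) {
      ms <- model$standardisation[[cl]]
      X[, cl] <- (X[, cl] - ms["mean"]) / ms["sd"]
    }
  }
  X
}

#' Score a cohort under a core model
#'
#' Computes each individual's linear predictor \eqn{\mu_i}, rate
#' \eqn{\eta_i = \exp(\mu_i)} and event risk \eqn{F_i(t^*) = 1 -
#' \exp(-\eta_i t^*)} at the model's horizon.
#'
#' @param model A [core_model()].
#' @param cohort A [cohort()] whose columns cover the model's weights.
#' @return A `risk_profile` data frame with columns `id`, `mu`, `eta`, `risk`.
#' @export
linear_predictor <- function(model, cohort) {
  stopifnot(inherits(model, "core_model"), inherits(cohort, "cohort"))
  X <- align_predictors(model, cohort)
  mu <- model$alpha + model$delta * drop(X %*% model$weights)
  out <- data.frame(id = cohort$ids, mu = mu, eta = exp(mu),
                    risk = event_risk(mu, model$horizon))
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' @rdname linear_predictor
#' @param object A `core_model`.
#' @param type One of `"lp"` (linear predictor), `"rate"`, `"risk"`.
#' @param t Horizon in years for `type = "risk"`; defaults to the model's.
#' @param ... Ignored.
#' @export
predict.core_model <- function(object, cohort, type = c("lp", "rate", "risk"),
                               t = object$horizon, ...) {
  type <- match.arg(type)
  rp <- linear_predictor(object, cohort)
  switch(type,
         lp = rp$mu,
         rate = rp$eta,
         risk = event_risk(rp$mu, t))
}

#' Event risk by time t under a constant rate
#'
#' \eqn{F(t) = 1 - \exp(-\exp(\mu) t)}: the exponential-model probability of
#' the event occurring by time `t` for an individual with log rate `mu`.
#' Strictly increasing in both arguments.
#'
#' @param mu Log event rate(s) (linear predictor).
#' @param t Time in years (> 0).
#' @return Probability in (0, 1), vectorised over `mu`.
#' @export
event_risk <- function(mu, t) {
  stopifnot(is.numeric(t), all(t > 0))
  -expm1(-exp(mu) * t)
}

# Inverse of event_risk in mu: the log rate whose risk at t is p.
risk_to_mu <- function(p, t) {
  stopifnot(all(p > 0 & p < 1))
  log(-log1p(-p) / t)
}

#' Analytic pairwise concordance of an exponential model
#'
#' Under exponential event times with no censoring, the probability that the
#' member of a random pair with the larger rate fails first is
#' \eqn{\max(\eta_i, \eta_j) / (\eta_i + \eta_j)}; averaging over all pairs
#' gives the model's concordance (C-index)
#' \deqn{C = \frac{2}{n(n-1)} \sum_{i<j} \frac{\max(\eta_i, \eta_j)}
#'   {\eta_i + \eta_j}.}
#' Tied rates contribute 1/2, so C = 0.5 for an uninformative model and
#' C < 1 always. The sum is evaluated in blocks so large cohorts do not
#' materialise the full pair matrix.
#'
#' @param eta Positive per-individual event rates (length >= 2).
#' @return The concordance in [0.5, 1).
#' @export
#' @examples
#' concordance_exponential(c(1, 3))  # 3/4
concordance_exponential <- function(eta) {
  if (length(eta) < 2L) {
    stop_stabsize("concordance needs at least two individuals", "state_error")
  }
  if (any(!is.finite(eta)) || any(eta <= 0)) {
    stop_stabsize("rates must be positive and finite", "validation_error")
  }
  # max/(sum) for a pair equals plogis(|log eta_i - log eta_j|)
  lam <- log(eta)
  n <- length(lam)
  total <- 0
  block <- max(1L, as.integer(2e6 %/% n))
  i <- 1L
  while (i < n) {
    idx <- i:min(i + block - 1L, n - 1L)
    d <- abs(outer(lam[idx], lam, "-"))
    keep <- outer(idx, seq_len(n), "<")
    total <- total + sum(stats::plogis(d[keep]))
    i <- i + block
  }
  total / choose(n, 2)
}

#' Write / read a core model as YAML
#'
#' A calibrated core model is a portable artefact: intercept, multiplier,
#' named weights, horizon and standardisation constants.
#'
#' @param model A `core_model`.
#' @param path File path.
#' @return `read_core_model` returns a `core_model`; `write_core_model`
#'   returns `path` invisibly.
#' @export
write_core_model <- function(model, path) {
  stopifnot(inherits(model, "core_model"))
  yaml::write_yaml(list(
    alpha = model$alpha, delta = model$delta,
    weights = as.list(model$weights), horizon = model$horizon,
    standardisation = lapply(model$standardisation, as.list)
  ), path)
  invisible(path)
}

#' @rdname write_core_model
#' @export
read_core_model <- function(path) {
  y <- yaml::read_yaml(path)
  core_model(alpha = y$alpha,
             weights = unlist(y$weights),
             delta = y$delta,
             horizon = y$horizon,
             standardisation = lapply(y$standardisation, function(p) {
               c(mean = p$mean, sd = p$sd)
             }))
}
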