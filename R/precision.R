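#' Variance of a new individual's linear predictor
#'
#' \eqn{\mathrm{var}(\hat\mu_{new}) = n^{-1} x_{new} I^{-1} x_{new}'}: the
#' anticipated sampling variance of the log event rate for an individual
#' with design row \eqn{x_{new} = (1, x_{1,new}, \dots, x_{P,new})} if the
#' core model were estimated on n participants. Scales exactly as 1/n.
#'
#' @param info A [unit_information()].
#' @param x_new Design row(s) *without* the intercept column: a numeric
#'   vector of length P or an n x P matrix.
#' @param n Development sample size (> 0).
#' @return Non-negative variance(s), one per row of `x_new`.
#' @export
prediction_variance <- function(info, x_new, n) {
  stopifnot(inherits(info, "unit_information"), n > 0)
  X <- design_with_intercept(if (is.null(dim(x_new))) t(x_new) else x_new)
  if (ncol(X) != ncol(info$inverse)) {
    stop_stabsize(sprintf("x_new has %d columns; information expects %d",
                          ncol(X) - 1L, ncol(info$inverse) - 1L),
                  "alignment_error")
  }
  rowSums((X %*% info$inverse) * X) / n
}

#' Risk-scale uncertainty interval for an individual
#'
#' Builds the normal-theory interval on the linear-predictor scale,
#' \eqn{\mu \pm z_{level} \sqrt{\mathrm{var}(\hat\mu)}}, and maps both ends
#' through the event-risk function \eqn{F(t) = 1 - \exp(-e^{\mu} t)}. The
#' map is strictly increasing, so the interval is a genuine interval on the
#' risk scale and always contains the true risk \eqn{F(\mu, t)}.
#'
#' @param mu True linear predictor(s).
#' @param var_mu Variance(s) of \eqn{\hat\mu} (>= 0).
#' @param t Time horizon in years.
#' @param level Confidence level (default 0.95, i.e. z = 1.96).
#' @return A data frame with columns `lower`, `upper`, `width`.
#' @export
#' @examples
#' uncertainty_interval(-2.3139, 0.01, t = 5)
uncertainty_interval <- function(mu, var_mu, t, level = 0.95) {
  stopifnot(all(var_mu >= 0), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- sqrt(var_mu)
  lower <- event_risk(mu - z * s, t)
  upper <- event_risk(mu + z * s, t)
  data.frame(lower = lower, upper = upper, width = upper - lower)
}

#' Sample an individual's risk uncertainty distribution
#'
#' Draws from the sampling distribution of the estimated risk,
#' \eqn{F(\mu + \sqrt{\mathrm{var}(\hat\mu)} Z, t)} with Z standard normal.
#' Per individual this is marginally identical to sampling the coefficient
#' vector \eqn{\hat\beta \sim N(\beta, \mathrm{var}(\hat\beta))} jointly
#' and scoring, because \eqn{x_{new}\hat\beta} is then exactly normal with
#' mean \eqn{\mu} and variance \eqn{x_{new} \mathrm{var}(\hat\beta)
#' x_{new}'}.
#'
#' @param mu True linear predictor (scalar).
#' @param var_mu Variance of \eqn{\hat\mu}.
#' @param t Horizon in years.
#' @param draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `draws` risk values.
#' @export
sample_uncertainty_distribution <- function(mu, var_mu, t, draws = 1000L,
                                            seed = 1L) {
  stopifnot(length(mu) == 1L, var_mu >= 0, draws >= 1)
  with_seed(seed, event_risk(mu + sqrt(var_mu) * stats::rnorm(draws), t))
}

#' Variance target achieving a risk-scale interval width
#'
#' Inverts the interval construction: finds the variance \eqn{s^2} such
#' that the `level` interval at the log rate \eqn{\mu = \ln(-\ln(1 -
#' p)/t)} corresponding to risk `risk_band` has exactly the requested
#' width on the risk scale. Width is strictly increasing in \eqn{s}, so the
#' root is unique; it is found by bracketed root finding to 1e-10.
#'
#' @param risk_band Risk value in (0, 1) at which the target applies.
#' @param target_width Desired interval width in (0, 1).
#' @param t Horizon in years.
#' @param level Confidence level.
#' @return The variance target \eqn{s^2}.
#' @export
required_variance_for_width <- function(risk_band, target_width, t,
                                        level = 0.95) {
  stopifnot(target_width > 0, target_width < 1)
  mu <- risk_to_mu(risk_band, t)
  width_at <- function(s) uncertainty_interval(mu, s^2, t, level)$width
  # Max attainable width: upper -> 1, lower -> 0 as s -> Inf
  if (width_at(50) <= target_width) {
    stop_stabsize(sprintf("width %.3f unattainable at risk %.3f",
                          target_width, risk_band),
                  "validation_error")
  }
  s <- stats::uniroot(function(s) width_at(s) - target_width,
                      lower = 0, upper = 50, tol = 1e-10)$root
  s^2
}

#' Sample size required for a variance target
#'
#' Rearranges the prediction-variance decomposition:
#' \eqn{n = \mathrm{var}(\hat\mu_{new})^{-1} x_{new} I^{-1} x_{new}'}.
#'
#' @param info A [unit_information()].
#' @param x_new Design row(s) without intercept (vector or matrix).
#' @param var_target Target variance(s) of \eqn{\hat\mu_{new}} (> 0).
#' @return A data frame with columns `n_raw` (exact) and `n` (rounded up).
#' @export
required_n <- function(info, x_new, var_target) {
  stopifnot(all(var_target > 0))
  quad <- prediction_variance(info, x_new, n = 1)
  raw <- quad / var_target
  data.frame(n_raw = raw, n = ceiling(raw))
}

#' Risk-band grid of interval-width targets
#'
#' @param bands Strictly increasing risk values in (0, 1).
#' @param target_widths Maximum interval width per band, in (0, 1).
#' @return A `sample_size_spec`.
#' @export
sample_size_spec <- function(bands = c(0.01, 0.025, 0.05, 0.10, 0.15, 0.20),
                             target_widths) {
  stopifnot(all(diff(bands) > 0), all(bands > 0 & bands < 1),
            length(target_widths) %in% c(1L, length(bands)),
            all(target_widths > 0 & target_widths < 1))
  if (length(target_widths) == 1L) {
    target_widths <- rep(target_widths, length(bands))
  }
  structure(list(bands = bands, target_widths = target_widths),
            class = "sample_size_spec")
}

#' Required sample size over a cohort
#'
#' Applies the required-n inversion to every individual. Two mappings from
#' width targets to variance targets are available:
#' \describe{
#'   \item{band (`spec` given)}{Each individual is assigned the band whose
#'     risk value is closest to their true risk (ties to the lower band);
#'     that band's width target is converted to a variance target *at the
#'     band's risk value*.}
#'   \item{per-individual (`spec = NULL`)}{A single `target_width` is
#'     converted to a variance target at each individual's own true risk.}
#' }
#' The overall recommendation is the ceiling of the maximum individual n —
#' the only combination rule that guarantees the width target for every
#' targeted individual.
#'
#' @param info A [unit_information()].
#' @param cohort A [cohort()].
#' @param model A [core_model()] defining true risks.
#' @param spec A [sample_size_spec()], or `NULL` for per-individual targets.
#' @param target_width Width target used when `spec` is `NULL`.
#' @param subset Optional logical/integer index restricting which
#'   individuals the target must hold for (e.g. true risk below 0.3).
#' @param level Confidence level.
#' @return A list with `per_individual` (data frame: id, risk, band,
#'   var_target, n_raw, n) and `overall_n`.
#' @export
cohort_required_n <- function(info, cohort, model, spec = NULL,
                              target_width = NULL, subset = NULL,
                              level = 0.95) {
  stopifnot(inherits(info, "unit_information"), inherits(cohort, "cohort"),
            inherits(model, "core_model"))
  rp <- linear_predictor(model, cohort)
  X <- model_design(cohort, model)
  if (!is.null(subset)) {
    if (length(subset) == 0 || (is.logical(subset) && !any(subset))) {
      stop_stabsize("empty subset", "validation_error")
    }
    X <- X[subset, , drop = FALSE]
    rp <- rp[subset, , drop = FALSE]
  }
  t <- model$horizon
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "sample_size_spec"))
    # nearest band in absolute risk difference; ties to the lower band
    band_idx <- vapply(rp$risk, function(r) {
      d <- abs(spec$bands - r)
      which(d == min(d))[1L]
    }, integer(1))
    band <- spec$bands[band_idx]
    var_target <- vapply(seq_along(spec$bands), function(j) {
      required_variance_for_width(spec$bands[j], spec$target_widths[j], t,
                                  level)
    }, numeric(1))[band_idx]
  } else {
    if (is.null(target_width)) {
      stop_stabsize("either spec or target_width must be given", "state_error")
    }
    band <- rp$risk
    var_target <- vapply(rp$mu, function(m) {
      s <- stats::uniroot(function(s) {
        uncertainty_interval(m, s^2, t, level)$width - target_width
      }, lower = 0, upper = 50, tol = 1e-10)$root
      s^2
    }, numeric(1))
  }
  rn <- required_n(info, X, var_target)
  per <- data.frame(id = rp$id, risk = rp$risk, band = band,
                    var_target = var_target, n_raw = rn$n_raw, n = rn$n)
  list(per_individual = per, overall_n = max(per$n))
}

#' Per-individual precision profile for a candidate sample size
#'
#' The central assessment object: for every individual in the cohort,
#' their true linear predictor and risk under the core model, the
#' anticipated variance of \eqn{\hat\mu} at development sample size `n`,
#' and the risk-scale uncertainty interval.
#'
#' @param model A [core_model()].
#' @param cohort A [cohort()] (used both as the information source when
#'   `info` is missing and as the target individuals).
#' @param n Development sample size.
#' @param info A [unit_information()]; computed from `cohort` and `model`
#'   when omitted (requires follow-up).
#' @param t Horizon in years (defaults to the model's).
#' @param level Confidence level.
#' @return A `precision_profile` data frame with columns `id`, `mu`,
#'   `risk`, `var_mu`, `lower`, `upper`, `width`, plus attributes `n`,
#'   `t`, `level`, and any cohort subgroups.
#' @export
precision_profile <- function(model, cohort, n, info = NULL,
                              t = model$horizon, level = 0.95) {
  stopifnot(inherits(model, "core_model"), inherits(cohort, "cohort"), n > 0)
  if (is.null(info)) info <- unit_information(cohort, model)
  rp <- linear_predictor(model, cohort)
  X <- model_design(cohort, model)
  v <- prediction_variance(info, X, n)
  ui <- uncertainty_interval(rp$mu, v, t, level)
  out <- data.frame(id = rp$id, mu = rp$mu, risk = event_risk(rp$mu, t),
                    var_mu = v, lower = ui$lower, upper = ui$upper,
                    width = ui$width)
  attr(out, "n") <- n
  attr(out, "t") <- t
  attr(out, "level") <- level
  attr(out, "subgroups") <- cohort$subgroups
  class(out) <- c("precision_profile", "data.frame")
  out
}

#' @export
print.precision_profile <- function(x, ...) {
  cat(sprintf(
    "<precision profile> %d individuals, n = %g, t = %g y, level = %g\n",
    nrow(x), attr(x, "n"), attr(x, "t"), attr(x, "level")))
  w <- four_num(x$width)
  cat(sprintf("  interval width: mean %.3f (min %.3f, med %.3f, max %.3f)\n",
              w["mean"], w["min"], w["median"], w["max"]))
  invisible(x)
}

#' @export
summary.precision_profile <- function(object, ...) {
  rbind(width = four_num(object$width),
        risk = four_num(object$risk),
        var_mu = four_num(object$var_mu))
}

#' @export
plot.precision_profile <- function(x, ...) {
  prediction_instability_plot(x, ...)
}
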