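#' Calibration target for a core model
#'
#' @param c_index Target concordance in (0.5, 1).
#' @param risk Target overall event risk at the horizon, in (0, 1).
#' @param tol_c,tol_risk Absolute convergence tolerances (default 0.001:
#'   tight enough to reproduce three-decimal reporting of the solution).
#' @param max_iter Cap on objective evaluations.
#' @return A `calibration_target`.
#' @export
calibration_target <- function(c_index, risk, tol_c = 0.001, tol_risk = 0.001,
                               max_iter = 200) {
  stopifnot(c_index >= 0.5, c_index < 1, risk > 0, risk < 1,
            tol_c > 0, tol_risk > 0, max_iter >= 1)
  structure(list(c_index = c_index, risk = risk, tol_c = tol_c,
                 tol_risk = tol_risk, max_iter = max_iter),
            class = "calibration_target")
}

# Solve alpha so the mean risk at horizon equals the target, delta fixed.
# mean(1 - exp(-t exp(alpha + delta z))) is strictly increasing in alpha.
solve_alpha <- function(z, delta, target_risk, horizon, tol) {
  f <- function(a) mean(event_risk(a + delta * z, horizon)) - target_risk
  stats::uniroot(f, lower = -40, upper = 20, tol = min(tol, 1e-8) / 10)$root
}

#' Calibrate a core model to a target C-index and overall risk
#'
#' Finds the intercept \eqn{\alpha} and multiplier \eqn{\delta} of
#' \eqn{\mu_i = \alpha + \delta \sum_p \beta_p x_{pi}} so the model attains
#' a specified concordance and mean event risk at the horizon on the given
#' cohort.
#'
#' Three methods are available:
#' \describe{
#'   \item{`"analytic"` (default)}{Nested one-dimensional root finds using
#'     the analytic no-censoring concordance of
#'     [concordance_exponential()]. That C is invariant to \eqn{\alpha}
#'     (the intercept cancels from every pairwise ratio) and non-decreasing
#'     in \eqn{\delta}, so the outer \eqn{\delta} root is unique and found
#'     by bracketed (Brent) root finding on a bracket grown by doubling from
#'     1 up to a cap of 64; the inner \eqn{\alpha} solve at that
#'     \eqn{\delta} is a second bracketed root find. Deterministic.}
#'   \item{`"score_mle"`}{Requires observed follow-up: fits the exponential
#'     regression \eqn{\mu_i = \alpha + \delta z_i} (with \eqn{z_i} the fixed
#'     weighted score) by maximum likelihood. This is the natural choice when
#'     a pilot dataset is at hand, since the fitted model automatically
#'     matches the cohort's observed concordance and overall risk; the
#'     achieved C reported is Harrell's C of the score on the observed data.}
#'   \item{`"harrell_sim"`}{C estimated as the average Harrell's C over
#'     simulated event/censoring realisations from the current model
#'     (censoring per `scheme`), alternating \eqn{(\delta | \alpha)} and
#'     \eqn{(\alpha | \delta)} to joint tolerance with a fixed seed.}
#' }
#'
#' @param cohort A [cohort()] providing the joint predictor distribution.
#' @param weights Named relative weights aligned to predictor columns.
#' @param target A [calibration_target()].
#' @param horizon Prediction time-point t* in years.
#' @param method Calibration method; see Details.
#' @param scheme A [censoring_scheme()], used by `"harrell_sim"`.
#' @param seed Seed for `"harrell_sim"` simulations.
#' @param n_sim Simulated realisations per C evaluation for `"harrell_sim"`.
#' @return A [core_model()] carrying a `calibration` attribute with the
#'   achieved C, achieved overall risk, evaluation count and method.
#' @export
#' @examples
#' ch <- cohort(cbind(z = rnorm(300)))
#' m <- calibrate(ch, c(z = 1), calibration_target(0.7, 0.39), horizon = 5)
#' attr(m, "calibration")
calibrate <- function(cohort, weights, target, horizon = 5,
                      method = c("analytic", "score_mle", "harrell_sim"),
                      scheme = NULL, seed = 1L, n_sim = 10L) {
  stopifnot(inherits(cohort, "cohort"), inherits(target, "calibration_target"))
  method <- match.arg(method)
  if (is.null(names(weights))) {
    stop_stabsize("weights must be named", "alignment_error")
  }
  X <- cohort$predictors[, names(weights), drop = FALSE]
  z <- drop(X %*% weights)
  evals <- 0L

  if (method == "score_mle") {
    if (is.null(cohort$time)) {
      stop_stabsize("score_mle calibration needs observed follow-up",
                    "state_error")
    }
    score_cohort <- cohort(cbind(z = z), time = cohort$time,
                           event = cohort$event)
    fit <- fit_exponential_mle(score_cohort)
    alpha <- unname(coef(fit)[1L])
    delta <- unname(coef(fit)[2L])
    achieved_c <- unname(survival::concordance(
      survival::Surv(cohort$time, cohort$event) ~ z, reverse = TRUE
    )$concordance)
    model <- core_model(alpha, weights, delta, horizon,
                        standardisation = cohort$standardisation)
    achieved_risk <- mean(linear_predictor(model, cohort)$risk)
    attr(model, "calibration") <- list(
      method = method, achieved_c = achieved_c, achieved_risk = achieved_risk,
      iterations = fit$iterations)
    return(model)
  }

  c_of_delta <- if (method == "analytic") {
    function(delta, alpha) {
      evals <<- evals + 1L
      concordance_exponential(exp(delta * z))
    }
  } else {
    if (is.null(scheme)) scheme <- censoring_scheme("none")
    function(delta, alpha) {
      evals <<- evals + 1L
      cs <- vapply(seq_len(n_sim), function(k) {
        m <- core_model(alpha, weights, delta, horizon,
                        standardisation = cohort$standardisation)
        te <- simulate_event_times(m, cohort, seed = seed + 7L * k)
        tc <- simulate_censoring(scheme, length(te), seed = seed + 7L * k + 3L)
        fu <- assemble_followup(te, tc)
        unname(survival::concordance(
          survival::Surv(fu$time, fu$event) ~ z, reverse = TRUE)$concordance)
      }, numeric(1))
      mean(cs)
    }
  }

  if (stats::sd(z) == 0 && target$c_index > 0.5) {
    stop_stabsize("flat linear predictor: target C-index unreachable",
                  "nonconvergence_error")
  }

  solve_delta <- function(alpha) {
    if (target$c_index == 0.5) return(0)
    delta_max <- 1
    while (c_of_delta(delta_max, alpha) < target$c_index) {
      delta_max <- delta_max * 2
      if (delta_max > 64) {
        stop_stabsize(sprintf(
          "target C-index %.3f unreachable for delta <= 64 (C(64) = %.4f)",
          target$c_index, c_of_delta(64, alpha)), "nonconvergence_error")
      }
      if (evals > target$max_iter) {
        stop_stabsize("max_iter exceeded while bracketing delta",
                      "nonconvergence_error")
      }
    }
    stats::uniroot(function(d) c_of_delta(d, alpha) - target$c_index,
                   lower = 0, upper = delta_max,
                   tol = min(target$tol_c, 1e-6) / 10)$root
  }

  if (method == "analytic") {
    # C does not depend on alpha: one outer solve, then one inner solve.
    delta <- solve_delta(alpha = 0)
    alpha <- solve_alpha(z, delta, target$risk, horizon, target$tol_risk)
  } else {
    alpha <- solve_alpha(z, 0, target$risk, horizon, target$tol_risk)
    delta <- 0
    for (it in seq_len(25L)) {
      delta_new <- solve_delta(alpha)
      alpha_new <- solve_alpha(z, delta_new, target$risk, horizon,
                               target$tol_risk)
      conv <- abs(delta_new - delta) < 1e-6 && abs(alpha_new - alpha) < 1e-6
      delta <- delta_new
      alpha <- alpha_new
      if (conv) break
      if (evals > target$max_iter) {
        stop_stabsize("max_iter exceeded in alternating calibration",
                      "nonconvergence_error")
      }
    }
  }

  model <- core_model(alpha, weights, delta, horizon,
                      standardisation = cohort$standardisation)
  achieved_c <- c_of_delta(delta, alpha)
  achieved_risk <- mean(linear_predictor(model, cohort)$risk)
  if (abs(achieved_c - target$c_index) > target$tol_c ||
      abs(achieved_risk - target$risk) > target$tol_risk) {
    stop_stabsize(sprintf(
      "calibration did not converge: achieved C = %.5f (target %.5f), risk = %.5f (target %.5f)",
      achieved_c, target$c_index, achieved_risk, target$risk),
      "nonconvergence_error")
  }
  attr(model, "calibration") <- list(
    method = method, achieved_c = achieved_c, achieved_risk = achieved_risk,
    iterations = evals)
  model
}

#' Equal-weight core model on the standardised scale
#'
#' Standardises the named continuous predictors, assigns every predictor a
#' relative weight of 1 — so a 1-SD increase carries the same predictive
#' effect for each — except declared null predictors (e.g. protected
#' characteristics carried only for fairness checks), whose weight is 0,
#' then calibrates \eqn{(\alpha, \delta)} with [calibrate()].
#'
#' @param cohort A [cohort()].
#' @param target A [calibration_target()].
#' @param horizon Time-point t* in years.
#' @param continuous Columns to standardise first; defaults to none (pass
#'   the already-standardised cohort, or name the continuous columns).
#' @param zero_weight Predictor columns given weight 0.
#' @param ... Passed to [calibrate()].
#' @return A calibrated [core_model()] with unit (or zero) weights.
#' @export
standardised_equal_weight_model <- function(cohort, target, horizon = 5,
                                            continuous = character(),
                                            zero_weight = character(), ...) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(continuous)) cohort <- standardise(cohort, continuous)
  w <- rep(1, ncol(cohort$predictors))
  names(w) <- colnames(cohort$predictors)
  w[zero_weight] <- 0
  if (all(w == 0) && target$c_index > 0.5) {
    stop_stabsize("all weights zero: target C-index unreachable",
                  "nonconvergence_error")
  }
  calibrate(cohort, w, target, horizon, ...)
}
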