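# Shared fixture builders for the test suite. All randomness is seeded.

# Small two-predictor cohort with exponential follow-up under a known model.
make_test_cohort <- function(n = 200, seed = 11, alpha = -2, delta = 0.5,
                             censor_rate = 0.1) {
  ch <- stabsize:::with_seed(seed, cohort(
    cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  ))
  m <- core_model(alpha = alpha, weights = c(x1 = 1, x2 = 2), delta = delta,
                  horizon = 5)
  sc <- if (censor_rate > 0) {
    censoring_scheme("exponential", rate = censor_rate)
  } else {
    censoring_scheme("none")
  }
  list(cohort = simulate_followup(ch, m, sc, seed = seed + 1),
       model = m)
}

# Intercept-only cohort (no predictors) with exponential event times.
make_null_cohort <- function(n, rate = 1, seed = 3, censoring = NULL) {
  te <- stabsize:::with_seed(seed, rexp(n, rate))
  if (is.null(censoring)) {
    cohort(matrix(0, n, 0), time = te, event = rep(1, n))
  } else {
    tc <- simulate_censoring(censoring, n, seed + 1)
    fu <- assemble_followup(te, tc)
    cohort(matrix(0, n, 0), time = fu$time, event = fu$event)
  }
}

null_model <- function(alpha = 0, horizon = 5) {
  core_model(alpha = alpha, weights = numeric(0), delta = 0, horizon = horizon)
}

# A fixed GBSG-like core model (no calibration) for large simulations.
fixed_gbsg_like_spec <- function(n) {
  spec <- gbsg_like_spec(n)
  spec$model <- core_model(
    alpha = -3.43, delta = 0.21,
    weights = c(age = -1, size = 0.5, nodes = 2, postmeno = 3,
                gradeg2 = 3, gradeg3 = 4),
    horizon = 5)
  spec$target <- NULL
  spec
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
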