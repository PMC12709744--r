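test_that("null-model calibration recovers the closed-form intercept", {
  ch <- cohort(cbind(z = rnorm(100)))
  m <- calibrate(ch, c(z = 1), calibration_target(0.5, 0.39), horizon = 5)
  expect_equal(m$delta, 0)
  # algebraic inversion of the mean-risk equation at delta = 0
  expect_equal(m$alpha, log(-log(1 - 0.39) / 5), tolerance = 1e-6)
  expect_equal(m$alpha, -2.3139, tolerance = 1e-4)
})

test_that("calibrated models re-score to their targets within tolerance", {
  ch <- stabsize:::with_seed(21, cohort(
    cbind(a = rnorm(400), b = rbinom(400, 1, 0.3))))
  tg <- calibration_target(0.70, 0.39)
  m <- calibrate(ch, c(a = 1, b = 2), tg, horizon = 5)
  rp <- linear_predictor(m, ch)
  expect_lt(abs(concordance_exponential(rp$eta) - 0.70), tg$tol_c)
  expect_lt(abs(mean(rp$risk) - 0.39), tg$tol_risk)
  cal <- attr(m, "calibration")
  expect_lt(abs(cal$achieved_c - 0.70), tg$tol_c)
  expect_lt(abs(cal$achieved_risk - 0.39), tg$tol_risk)
})

test_that("delta-weights scale invariance and alpha-independence hold", {
  ch <- stabsize:::with_seed(22, cohort(cbind(a = rnorm(300))))
  tg <- calibration_target(0.65, 0.30)
  m1 <- calibrate(ch, c(a = 1), tg, horizon = 5)
  m2 <- calibrate(ch, c(a = 2), tg, horizon = 5)
  # doubling the weights halves the recovered delta; mu is unchanged
  expect_equal(m2$delta, m1$delta / 2, tolerance = 1e-4)
  expect_equal(linear_predictor(m2, ch)$mu, linear_predictor(m1, ch)$mu,
               tolerance = 1e-4)
  # the outer delta solution does not depend on the risk target (alpha
  # cancels from the analytic concordance)
  m3 <- calibrate(ch, c(a = 1), calibration_target(0.65, 0.10), horizon = 5)
  expect_equal(m3$delta, m1$delta, tolerance = 1e-8)
})

test_that("unreachable targets raise non-convergence errors", {
  flat <- cohort(cbind(z = rep(1, 50)))
  expect_error(
    calibrate(flat, c(z = 1), calibration_target(0.7, 0.39)),
    class = "nonconvergence_error")
})

test_that("equal-weight standardised calibration honours zero weights", {
  ch <- stabsize:::with_seed(23, cohort(
    cbind(a = rnorm(300, 50, 10), b = rnorm(300, 10, 2),
          sex = rbinom(300, 1, 0.5))))
  tg <- calibration_target(0.70, 0.39)
  m <- standardised_equal_weight_model(ch, tg, horizon = 5,
                                       continuous = c("a", "b"))
  expect_equal(unname(m$weights), c(1, 1, 1))
  rp <- linear_predictor(m, standardise(ch, c("a", "b")))
  expect_lt(abs(concordance_exponential(rp$eta) - 0.70), tg$tol_c)
  expect_lt(abs(mean(rp$risk) - 0.39), tg$tol_risk)
  # protected characteristic carried with zero weight: C driven by the rest
  mz <- standardised_equal_weight_model(ch, tg, horizon = 5,
                                        continuous = c("a", "b"),
                                        zero_weight = "sex")
  expect_equal(unname(mz$weights["sex"]), 0)
  expect_lt(abs(attr(mz, "calibration")$achieved_c - 0.70), tg$tol_c)
  # all weights zero reduces to the null closed form at C = 0.5
  m0 <- standardised_equal_weight_model(
    ch, calibration_target(0.5, 0.39), horizon = 5,
    continuous = c("a", "b"), zero_weight = c("a", "b", "sex"))
  expect_equal(m0$delta, 0)
  expect_equal(m0$alpha, log(-log(0.61) / 5), tolerance = 1e-6)
})

test_that("score-MLE calibration reproduces the published pilot model", {
  ch <- gbsg_pilot_cohort()
  w <- c(age = -1, size = 0.5, nodes = 2, postmeno = 3, grade2 = 3,
         grade3 = 4)
  m <- calibrate(ch, w, calibration_target(0.70, 0.39), horizon = 5,
                 method = "score_mle")
  # agreement to the printed three- / two-decimal precision
  expect_lt(abs(m$alpha - (-3.429)), 5.1e-4)
  expect_lt(abs(m$delta - 0.208), 5.1e-4)
  cal <- attr(m, "calibration")
  expect_lt(abs(cal$achieved_c - 0.70), 5.1e-3)
  expect_lt(abs(cal$achieved_risk - 0.39), 5.1e-3)
  expect_error(
    calibrate(cohort(cbind(z = rnorm(10))), c(z = 1),
              calibration_target(0.7, 0.39), method = "score_mle"),
    class = "state_error")
})

test_that("simulated-Harrell calibration converges near the analytic one", {
  ch <- stabsize:::with_seed(24, cohort(cbind(a = rnorm(250))))
  tg <- calibration_target(0.65, 0.39, tol_c = 0.01, tol_risk = 0.005)
  m <- calibrate(ch, c(a = 1), tg, horizon = 5, method = "harrell_sim",
                 scheme = censoring_scheme("none"), seed = 7, n_sim = 8)
  ma <- calibrate(ch, c(a = 1), calibration_target(0.65, 0.39), horizon = 5)
  # without censoring the two C definitions estimate the same quantity
  expect_equal(m$delta, ma$delta, tolerance = 0.15)
  expect_lt(abs(attr(m, "calibration")$achieved_risk - 0.39), tg$tol_risk)
})
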