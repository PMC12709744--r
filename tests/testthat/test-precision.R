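test_that("prediction variance is the quadratic form with exact 1/n scaling", {
  ch1 <- cohort(matrix(0, 2, 0), time = c(1, 1), event = c(1, 1))
  ui1 <- unit_information(ch1, null_model(alpha = 0))  # I = [[1]]
  expect_equal(prediction_variance(ui1, matrix(0, 1, 0), 355), 1 / 355)
  # exact scaling across an n grid
  fx <- make_test_cohort(n = 150, seed = 61)
  ui <- unit_information(fx$cohort, fx$model)
  X <- fx$cohort$predictors
  v355 <- prediction_variance(ui, X, 355)
  # n-free quadratic form is computed once, so scaling is exact up to
  # floating-point reassociation
  expect_equal(prediction_variance(ui, X, 920) * 920, v355 * 355,
               tolerance = 1e-14)
  expect_true(all(v355 >= 0))
  # independent triple-loop oracle for the quadratic form
  x <- X[7, ]
  xr <- c(1, x)
  brute <- 0
  for (j in seq_along(xr)) {
    for (k in seq_along(xr)) {
      brute <- brute + xr[j] * ui$inverse[j, k] * xr[k]
    }
  }
  expect_equal(unname(prediction_variance(ui, x, 500)), unname(brute) / 500,
               tolerance = 1e-12)
  expect_error(prediction_variance(ui, c(1, 2, 3), 100),
               class = "alignment_error")
})

test_that("uncertainty intervals map the mu interval through the risk function", {
  # frozen worked example, recomputed here from the defining formulas
  mu <- -2.3139
  s <- sqrt(0.01)
  z <- qnorm(0.975)
  lo <- 1 - exp(-5 * exp(mu - z * s))
  hi <- 1 - exp(-5 * exp(mu + z * s))
  ui <- uncertainty_interval(mu, 0.01, t = 5, level = 0.95)
  expect_equal(ui$lower, lo, tolerance = 1e-6)
  expect_equal(ui$upper, hi, tolerance = 1e-6)
  expect_equal(ui$lower, 0.334, tolerance = 1e-3)
  expect_equal(ui$upper, 0.452, tolerance = 1e-3)
  expect_equal(ui$width, 0.118, tolerance = 1e-3)
  # degenerate at zero variance; contains the truth; monotone in variance
  ui0 <- uncertainty_interval(mu, 0, t = 5)
  expect_equal(ui0$lower, ui0$upper)
  expect_equal(ui0$lower, event_risk(mu, 5))
  for (m in c(-4, -2.3139, -1)) {
    w1 <- uncertainty_interval(m, 0.01, 5)$width
    w4 <- uncertainty_interval(m, 0.04, 5)$width
    expect_gt(w4, w1)
    iv <- uncertainty_interval(m, 0.01, 5)
    expect_true(iv$lower <= event_risk(m, 5) && event_risk(m, 5) <= iv$upper)
    expect_true(iv$lower >= 0 && iv$upper <= 1)
  }
})

test_that("uncertainty draws are seeded and match the analytic interval", {
  r1 <- sample_uncertainty_distribution(-2.3139, 0.01, 5, draws = 100,
                                        seed = 8)
  r2 <- sample_uncertainty_distribution(-2.3139, 0.01, 5, draws = 100,
                                        seed = 8)
  expect_identical(r1, r2)
  expect_equal(sample_uncertainty_distribution(-2, 0, 5, draws = 10),
               rep(event_risk(-2, 5), 10))
  big <- sample_uncertainty_distribution(-2.3139, 0.01, 5, draws = 100000,
                                         seed = 9)
  iv <- uncertainty_interval(-2.3139, 0.01, 5)
  q <- quantile(big, c(0.025, 0.975), names = FALSE)
  expect_equal(q[1], iv$lower, tolerance = 0.005)
  expect_equal(q[2], iv$upper, tolerance = 0.005)
})

test_that("width-to-variance inversion round-trips and hits the worked value", {
  for (rb in c(0.05, 0.2, 0.39)) {
    s2 <- required_variance_for_width(rb, 0.118, t = 5)
    w <- uncertainty_interval(stabsize:::risk_to_mu(rb, 5), s2, 5)$width
    expect_equal(w, 0.118, tolerance = 1e-8)
  }
  # inverse of the worked interval example
  expect_equal(required_variance_for_width(0.39, 0.118, t = 5), 0.01,
               tolerance = 2e-4)
  # small widths need small variances
  expect_lt(required_variance_for_width(0.2, 0.001, t = 5), 1e-5)
})

test_that("required_n inverts prediction_variance exactly", {
  fx <- make_test_cohort(n = 100, seed = 62)
  ui <- unit_information(fx$cohort, fx$model)
  x <- fx$cohort$predictors[3, ]
  rn <- required_n(ui, x, 0.015)
  expect_equal(prediction_variance(ui, x, rn$n_raw), 0.015, tolerance = 1e-12)
  expect_equal(rn$n, ceiling(rn$n_raw))
  # intercept-only, I = [[1]], v = 0.01 -> n = 100
  ch1 <- cohort(matrix(0, 2, 0), time = c(1, 1), event = c(1, 1))
  ui1 <- unit_information(ch1, null_model(alpha = 0))
  expect_equal(required_n(ui1, matrix(0, 1, 0), 0.01)$n_raw, 100)
})

test_that("cohort-level required n: bands, monotonicity, exact width scaling", {
  fx <- make_test_cohort(n = 200, seed = 63)
  ui <- unit_information(fx$cohort, fx$model)
  spec <- sample_size_spec(bands = c(0.05, 0.1, 0.2, 0.4), target_widths = 0.2)
  res <- cohort_required_n(ui, fx$cohort, fx$model, spec = spec)
  expect_true(all(res$per_individual$band %in% spec$bands))
  expect_equal(res$overall_n, max(res$per_individual$n))
  # tightening every band's width target cannot decrease the overall n
  tight <- sample_size_spec(bands = spec$bands, target_widths = 0.1)
  res_tight <- cohort_required_n(ui, fx$cohort, fx$model, spec = tight)
  expect_gte(res_tight$overall_n, res$overall_n)
  # per-individual targets: n scales exactly as 1/s^2 when widths relax,
  # verified by recomputation rather than a linear approximation
  r1 <- cohort_required_n(ui, fx$cohort, fx$model, target_width = 0.1)
  r2 <- cohort_required_n(ui, fx$cohort, fx$model, target_width = 0.2)
  v1 <- r1$per_individual$var_target
  v2 <- r2$per_individual$var_target
  expect_equal(r2$per_individual$n_raw, r1$per_individual$n_raw * v1 / v2,
               tolerance = 1e-8)
  # uniform cohort: everyone needs the same n
  chu <- cohort(cbind(x1 = rep(0.5, 30), x2 = rep(1, 30)),
                time = rep(2, 30), event = rep(1, 30))
  uiu <- unit_information(fx$cohort, fx$model)  # info from varied cohort
  ru <- cohort_required_n(uiu, chu, fx$model, target_width = 0.2)
  expect_equal(length(unique(round(ru$per_individual$n_raw, 9))), 1L)
  expect_equal(ru$overall_n, ru$per_individual$n[1])
  expect_error(
    cohort_required_n(ui, fx$cohort, fx$model, spec = spec,
                      subset = rep(FALSE, 200)),
    class = "validation_error")
})

test_that("band assignment picks the closest band, ties to the lower", {
  fx <- make_test_cohort(n = 50, seed = 64)
  ui <- unit_information(fx$cohort, fx$model)
  # craft a model whose risks we control through alpha at delta = 0
  m <- core_model(alpha = stabsize:::risk_to_mu(0.075, 5),
                  weights = c(x1 = 0, x2 = 0), delta = 0, horizon = 5)
  spec <- sample_size_spec(bands = c(0.05, 0.1), target_widths = 0.15)
  res <- cohort_required_n(ui, fx$cohort, m, spec = spec)
  # 0.075 is equidistant from 0.05 and 0.10: the tie goes to the lower band
  expect_true(all(res$per_individual$band == 0.05))
})

test_that("precision profiles assemble truth, variance and intervals", {
  fx <- make_test_cohort(n = 150, seed = 65)
  ui <- unit_information(fx$cohort, fx$model)
  pp <- precision_profile(fx$model, fx$cohort, n = 355, info = ui)
  expect_s3_class(pp, "precision_profile")
  expect_equal(nrow(pp), 150)
  expect_equal(pp$risk, event_risk(pp$mu, 5))
  expect_true(all(pp$lower <= pp$risk & pp$risk <= pp$upper))
  expect_equal(pp$width, pp$upper - pp$lower)
  # mu-scale half-widths scale exactly as 1/sqrt(n)
  pp920 <- precision_profile(fx$model, fx$cohort, n = 920, info = ui)
  expect_equal(sqrt(pp920$var_mu) * sqrt(920), sqrt(pp$var_mu) * sqrt(355),
               tolerance = 1e-12)
  expect_true(all(pp920$width < pp$width))
})
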