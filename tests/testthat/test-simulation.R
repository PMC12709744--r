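test_that("event-time simulation is seeded inverse-CDF sampling", {
  ch <- cohort(cbind(z = rep(0, 5000)))
  m <- core_model(alpha = 0, weights = c(z = 1), delta = 0, horizon = 5)
  t1 <- simulate_event_times(m, ch, seed = 101)
  t2 <- simulate_event_times(m, ch, seed = 101)
  expect_identical(t1, t2)
  # eta = 1 for everyone: mean time 1 within 3 SE (exponential SD = 1)
  expect_lt(abs(mean(t1) - 1), 3 / sqrt(5000))
  # Kolmogorov-Smirnov against the exponential CDF at alpha = 0.01
  ks <- suppressWarnings(ks.test(t1, pexp, 1))
  expect_gt(ks$p.value, 0.01)
  # the global RNG stream is untouched
  before <- stabsize:::with_seed(1, runif(1))
  set.seed(1)
  invisible(simulate_event_times(m, ch, seed = 77))
  expect_identical(runif(1), before)
})

test_that("simulated event fractions match the model's risk", {
  ch <- stabsize:::with_seed(31, cohort(cbind(z = rnorm(10000))))
  m <- calibrate(ch, c(z = 1), calibration_target(0.5, 0.39), horizon = 5)
  tt <- simulate_event_times(m, ch, seed = 32)
  expect_lt(abs(mean(tt <= 5) - 0.39), 3 * sqrt(0.39 * 0.61 / 10000))
})

test_that("censoring schemes have the declared supports and moments", {
  adm <- simulate_censoring(censoring_scheme("administrative", t_max = 7.28),
                            5, seed = 1)
  expect_equal(adm, rep(7.28, 5))
  win <- simulate_censoring(
    censoring_scheme("window", t_min = 2, t_max = 7.28), 5000, seed = 2)
  expect_gte(min(win), 2)
  expect_lte(max(win), 7.28)
  ex <- simulate_censoring(censoring_scheme("exponential", rate = 0.1),
                           5000, seed = 3)
  expect_lt(abs(mean(ex) - 10), 3 * 10 / sqrt(5000))
  expect_true(all(is.infinite(
    simulate_censoring(censoring_scheme("none"), 3, seed = 4))))
  # partial administrative mass in the window scheme
  mix <- simulate_censoring(
    censoring_scheme("window", t_min = 2, t_max = 7.28, p_uniform = 0.5),
    4000, seed = 5)
  expect_lt(abs(mean(mix == 7.28) - 0.5), 3 * 0.5 / sqrt(4000))
})

test_that("assemble_followup takes minima, flags ties as events, conserves counts", {
  fu <- assemble_followup(c(3, 5, 2), c(5, 3, 2))
  expect_equal(fu$time, c(3, 3, 2))
  expect_equal(fu$event, c(1, 0, 1))
  expect_error(assemble_followup(1:3, 1:2), class = "validation_error")
  # no censoring: everyone is an event
  fu2 <- assemble_followup(c(1, 2), c(Inf, Inf))
  expect_equal(fu2$event, c(1, 1))
  # events + censorings = n, and window censoring never censors before t_min
  ch <- stabsize:::with_seed(33, cohort(cbind(z = rnorm(2000))))
  m <- core_model(alpha = -2.3, weights = c(z = 1), delta = 0.3, horizon = 5)
  sc <- censoring_scheme("window", t_min = 2, t_max = 7.28)
  fc <- simulate_followup(ch, m, sc, seed = 34)
  expect_equal(sum(fc$event == 1) + sum(fc$event == 0), 2000)
  expect_gte(min(fc$time[fc$event == 0]), 2)
})

test_that("fixture generation is reproducible and respects its spec", {
  spec <- fixture_spec(
    n = 3000,
    continuous = list(a = list(mean = 10, sd = 2),
                      b = list(mean = 0, sd = 1)),
    correlation = diag(2),
    binary = list(d = 0.3),
    model = core_model(alpha = -2.5, weights = c(a = 1, b = 1, d = 1),
                       delta = 0.2, horizon = 5),
    scheme = censoring_scheme("none"),
    standardise_continuous = FALSE)
  f1 <- generate_fixture(spec, seed = 9)
  f2 <- generate_fixture(spec, seed = 9)
  expect_identical(f1$cohort$predictors, f2$cohort$predictors)
  expect_identical(f1$cohort$time, f2$cohort$time)
  P <- f1$cohort$predictors
  expect_lt(abs(mean(P[, "a"]) - 10), 3 * 2 / sqrt(3000))
  expect_lt(abs(cor(P[, "a"], P[, "b"])), 3 / sqrt(3000))
  expect_lt(abs(mean(P[, "d"]) - 0.3), 3 * sqrt(0.3 * 0.7 / 3000))
  expect_error(
    fixture_spec(n = 10,
                 continuous = list(a = list(mean = 0, sd = 1),
                                   b = list(mean = 0, sd = 1)),
                 correlation = matrix(c(1, 2, 2, 1), 2, 2)),
    class = "validation_error")
})

test_that("the GBSG-like preset emulates the pilot cohort's follow-up", {
  fx <- generate_fixture(gbsg_like_spec(n = 4000), seed = 51)
  s <- summarise_followup(fx$cohort)
  expect_gt(s$mean_followup, 3.2)
  expect_lt(s$mean_followup, 4.0)
  expect_lte(s$max_followup, 7.28)
  # the calibrated preset model hits its targets on the generated cohort
  cal <- attr(fx$model, "calibration")
  expect_equal(cal$achieved_c, 0.70, tolerance = 0.001)
  expect_equal(cal$achieved_risk, 0.39, tolerance = 0.001)
  # correlated predictors: size-nodes correlation near its spec value
  # (absolute band of ~4 sampling SEs at n = 4000)
  expect_lt(abs(cor(fx$cohort$predictors[, "size"],
                    fx$cohort$predictors[, "nodes"]) - 0.41), 0.05)
})
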