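test_that("correlogram returns a valid correlation sequence", {
  x <- simulate_ar(ar_model(0.5, 1), 5000, seed = 11)
  a <- correlogram(x, 30)
  expect_identical(a$lag, 0:30)
  expect_equal(a$value[1], 1)
  expect_true(all(abs(a$value) <= 1))
  expect_equal(a$ci_bound[1], qnorm(0.975) / sqrt(5000))

  p <- correlogram(x, 30, type = "pacf")
  expect_identical(p$lag, 1:30)
  expect_true(all(abs(p$value) <= 1))

  expect_error(correlogram(rep(2, 100), 10), "constant")
  expect_error(correlogram(x, 0), "positive integer")
  expect_error(correlogram(x[1:10], 10), "longer")
})

test_that("AR(1) autocorrelation decays geometrically", {
  x <- simulate_ar(ar_model(0.5, 1), 1e5, seed = 21)
  a <- correlogram(x, 6)
  expect_equal(a$value[a$lag %in% 1:6], 0.5^(1:6), tolerance = 0.02)
})

test_that("PACF identifies AR structure and is silent for white noise", {
  x <- simulate_ar(ar_model(0.5, 1), 1e5, seed = 22)
  p <- correlogram(x, 10, type = "pacf")
  expect_equal(p$value[1], 0.5, tolerance = 0.02)
  expect_true(all(abs(p$value[-1]) < 3 * p$ci_bound[1]))

  w <- simulate_ar(ar_model(numeric(0), 1), 1e5, seed = 23)
  pw <- correlogram(w, 20, type = "pacf")
  # pointwise 95% bound: expect about 5% exceedances, certainly not many
  expect_lt(mean(abs(pw$value) > pw$ci_bound), 0.25)
})

test_that("Durbin-Levinson PACF agrees with the regression definition", {
  x <- simulate_ar(ar_model(c(0.5, 0.3), 1), 2000, seed = 31)
  p <- correlogram(x, 8, type = "pacf")
  expect_equal(p$value, brute_pacf(x, 8), tolerance = 0.02)
})

test_that("fit_ar selects the generating order and recovers coefficients", {
  w <- simulate_ar(ar_model(numeric(0), 2), 1e5, seed = 41)
  m0 <- fit_ar(w)
  expect_identical(m0$order, 0L)
  expect_equal(m0$innovation_sd, 2, tolerance = 0.05)

  x <- simulate_ar(ar_model(c(0.5, 0.3), 1), 1e5, seed = 42)
  m2 <- fit_ar(x)
  expect_identical(m2$order, 2L)
  expect_lt(max(abs(m2$coefficients - c(0.5, 0.3))), 0.02)

  x7 <- simulate_ar(ar_model(ar7_coefs(), 1), 2e5, seed = 43)
  expect_identical(fit_ar(x7)$order, 7L)

  expect_error(fit_ar(rep(1, 1000)), "constant")
})

test_that("fit_ar recovers a detectable order in most realizations", {
  # lag-3 coefficient 0.15 is ~5x the single-lag null bound at n = 1e4
  truth <- ar_model(c(0.3, 0.1, 0.15), 1)
  hits <- vapply(1:20, function(s) {
    fit_ar(simulate_ar(truth, 1e4, seed = 100 + s))$order == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("simulate_ar is reproducible, stationary, and validates input", {
  m <- ar_model(0.9, 1)
  x1 <- simulate_ar(m, 1000, seed = 5)
  x2 <- simulate_ar(m, 1000, seed = 5)
  expect_identical(x1, x2)
  expect_false(identical(x1, simulate_ar(m, 1000, seed = 6)))

  # closed-form stationary variance 1 / (1 - 0.81)
  xl <- simulate_ar(m, 2e5, seed = 7)
  expect_equal(var(xl), 1 / (1 - 0.81), tolerance = 0.05)

  # order 0 reduces to i.i.d. draws with the innovation scale
  x0 <- simulate_ar(ar_model(numeric(0), 3), 5e4, seed = 8)
  expect_equal(sd(x0), 3, tolerance = 0.05)

  expect_error(ar_model(1.05, 1), "stationary")
  expect_error(simulate_ar(m, 1000, seed = 1, burn_in = 2), "burn_in")
  expect_error(simulate_ar(m, 1000), "seed")
})

test_that("simulated noise reproduces the model's theoretical correlations", {
  m <- ar_model(c(0.6, -0.2), 1)
  x <- simulate_ar(m, 1e5, seed = 51)
  theo <- as.numeric(stats::ARMAacf(ar = m$coefficients, lag.max = 10))
  a <- correlogram(x, 10)
  expect_lt(max(abs(a$value - theo)), 0.02)
  expect_equal(ar_marginal_sd(m), sd(x), tolerance = 0.02)
})
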