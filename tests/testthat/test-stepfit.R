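test_that("design_matrix builds Heaviside indicator columns", {
  expect_identical(design_matrix(4, integer(0)),
                   matrix(1, 4, 1, dimnames = list(NULL, "baseline")))
  X <- design_matrix(5, 3)
  expect_equal(unname(X[, 2]), c(0, 0, 0, 1, 1))
  X3 <- design_matrix(100, c(20, 50, 80))
  expect_identical(qr(X3)$rank, 4L)
  expect_error(design_matrix(10, c(4, 4)), "Duplicate")
  expect_error(design_matrix(10, 10), "inside")
})

test_that("OLS step estimates are segment-mean differences", {
  set.seed(71)
  y <- staircase(c(40, 30, 50), c(2, -1.5)) + rnorm(120, sd = 0.5)
  steps <- c(40, 70)
  f <- fit_ols(y, steps)
  segs <- list(y[1:40], y[41:70], y[71:120])
  means <- vapply(segs, mean, numeric(1))
  expect_equal(f$model$baseline, means[1])
  expect_equal(f$model$step_sizes, diff(means))

  # flat trace, no steps: baseline is the sample mean
  f0 <- fit_ols(y)
  expect_equal(f0$model$baseline, mean(y))
  expect_length(f0$model$step_indices, 0)
})

test_that("a noiseless staircase is interpolated exactly", {
  y <- staircase(c(60, 50, 70), c(2, -1))
  f <- fit_ols(y, c(60, 110))
  expect_equal(f$model$step_sizes, c(2, -1))
  expect_equal(max(abs(residuals(f, "response"))), 0)
  g <- fit_gls(y, c(60, 110), ar_model(c(0.4, 0.2), 1))
  expect_equal(g$model$step_sizes, c(2, -1))
})

test_that("engine matches the dense least-squares oracle", {
  set.seed(72)
  y <- staircase(c(60, 50, 70), c(2, -1)) + rnorm(180, sd = 0.3)
  steps <- c(60, 110)

  f <- fit_ols(y, steps)
  lf <- lm_step_oracle(y, steps)
  expect_equal(c(f$model$baseline, f$model$step_sizes), unname(coef(lf)),
               tolerance = 1e-10)
  expect_equal(f$standard_errors, unname(sqrt(diag(vcov(lf)))),
               tolerance = 1e-10)

  nm <- ar_model(c(0.5, 0.2), 1)
  g <- fit_gls(y, steps, nm)
  lg <- lm_step_oracle(y, steps, nm)
  expect_equal(c(g$model$baseline, g$model$step_sizes), unname(coef(lg)),
               tolerance = 1e-10)
  expect_equal(g$standard_errors, unname(sqrt(diag(vcov(lg)))),
               tolerance = 1e-10)
  np <- length(y) - nm$order
  rss <- sum(resid(lg)^2)
  expect_equal(g$loglik, -np / 2 * (log(2 * pi * rss / np) + 1))
  expect_equal(g$sigma2, rss / np)
})

test_that("GLS with order-0 noise is numerically identical to OLS", {
  set.seed(73)
  y <- staircase(c(100, 80, 90), c(1, 1)) + rnorm(270, sd = 0.4)
  f <- fit_ols(y, c(100, 180))
  g <- fit_gls(y, c(100, 180), ar_model(numeric(0), 1))
  expect_identical(g$model$step_sizes, f$model$step_sizes)
  expect_identical(g$standard_errors, f$standard_errors)
  expect_identical(g$loglik, f$loglik)
  expect_identical(g$bic, f$bic)
})

test_that("the whitening filter behaves as the AR polynomial in backshift", {
  x <- rnorm(50)
  expect_identical(co_transform(x, ar_model(numeric(0), 1)), x)

  ones <- rep(1, 20)
  z <- co_transform(ones, ar_model(0.3, 1))
  expect_length(z, 19)
  expect_equal(z, rep(0.7, 19))

  # filtering AR noise by its own model leaves white innovations
  m7 <- ar_model(ar7_coefs(), 1)
  x7 <- simulate_ar(m7, 5e4, seed = 74)
  w <- co_transform(x7, m7)
  expect_identical(fit_ar(w)$order, 0L)
  expect_equal(sd(w), 1, tolerance = 0.02)
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 5, 1000)
  expect_equal(ic$aic, 210)
  expect_equal(ic$bic, 200 + 5 * log(1000))

  ic1 <- information_criteria(-50, 1, 200)
  expect_equal(ic1$bic - ic1$aic, log(200) - 2)

  # per-parameter BIC penalty exceeds the AIC penalty exactly for n > 7
  crossover <- max(which(vapply(1:20, function(n) log(n) <= 2, logical(1))))
  expect_identical(crossover, 7L)
  expect_error(information_criteria(-10, 0, 10), "at least 1")
})

test_that("adding a candidate step never decreases the likelihood", {
  set.seed(75)
  y <- staircase(c(150, 150, 150), c(1, -1)) + rnorm(450, sd = 0.5)
  nm <- ar_model(0.4, 1)
  nested <- list(integer(0), 150, c(150, 300), c(100, 150, 300),
                 c(100, 150, 220, 300))
  ll <- vapply(nested, function(s) fit_gls(y, s, nm)$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("GLS standard errors are calibrated under correlated noise", {
  # one unit step in AR(1) noise; OLS ignores the correlation and its
  # nominal 95% intervals undercover badly, GLS intervals do not
  nm <- ar_model(0.6, 0.3)
  inside <- function(fit) {
    abs(fit$model$step_sizes[1] - 1) <= qnorm(0.975) * fit$standard_errors[2]
  }
  res <- vapply(1:150, function(s) {
    y <- c(rep(0, 400), rep(1, 400)) + simulate_ar(nm, 800, seed = 7000 + s)
    c(gls = inside(fit_gls(y, 400, nm)), ols = inside(fit_ols(y, 400)))
  }, logical(2))
  expect_gte(mean(res["gls", ]), 0.90)
  expect_lte(mean(res["ols", ]), 0.85)
})

test_that("invalid step sets are rejected with a useful error", {
  y <- rnorm(50)
  expect_error(fit_ols(y, c(10, 10)), "Duplicate")
  expect_error(fit_ols(y, 60), "inside")
  expect_error(fit_ols(y, 0), "inside")
})

test_that("backward elimination recovers clean steps and rejects noise", {
  y <- staircase(c(200, 180, 220), c(1, -2))
  cand <- c(150, 200, 380, 500)
  f <- backward_select(y, cand)
  expect_identical(f$model$step_indices, c(200L, 380L))
  expect_equal(f$model$step_sizes, c(1, -2))

  set.seed(76)
  noise_only <- rnorm(2000)
  f0 <- backward_select(noise_only, c(400, 900, 1300))
  expect_length(f0$model$step_indices, 0)
  # the path records one round per elimination plus the empty model
  expect_identical(nrow(f0$path), 4L)
  expect_identical(f0$path$n_steps, c(3L, 2L, 1L, 0L))

  # empty candidate set: baseline-only fit
  fe <- backward_select(noise_only, integer(0))
  expect_length(fe$model$step_indices, 0)
  expect_equal(fe$model$baseline, mean(noise_only))
})

test_that("elimination-path updates match full refits", {
  set.seed(77)
  y <- staircase(c(150, 150, 150, 150), c(1, -1, 2)) +
    simulate_ar(ar_model(0.5, 0.4), 600, seed = 78)
  f <- backward_select(y, c(150, 300, 450, 520))
  noise <- f$noise
  expect_gte(noise$order, 1L)
  # every BIC on the recorded path equals the BIC of an explicit fit of the
  # model present at that round, under the same whitening model
  cand <- c(150L, 300L, 450L, 520L)
  for (r in seq_len(nrow(f$path))) {
    removed <- f$path$removed_index[seq_len(r - 1)]
    steps <- setdiff(cand, removed[!is.na(removed)])
    ref <- fit_gls(y, steps, noise)
    expect_equal(f$path$bic[r], ref$bic, tolerance = 1e-8)
  }
  # the per-round re-estimation option runs and returns a comparable model
  f2 <- backward_select(y, c(150, 300, 450, 520), reestimate_ar = TRUE)
  expect_s3_class(f2, "step_fit")
  expect_true(all(f2$model$step_indices %in% cand))
})

test_that("detect_steps runs the full pipeline end to end", {
  sim <- render_trace(step_spec(c(0.5, 0.6, 0.5, 0.4), c(1, -1, 2),
                                sampling_rate = 500))
  fit <- detect_steps(sim$trace)
  expect_identical(fit$model$step_indices, sim$truth$step_indices)
  expect_equal(fit$model$step_sizes, sim$truth$step_sizes)

  expect_error(detect_steps(rnorm(50)), "at least 100")
  expect_warning(f0 <- detect_steps(rep(1, 500)), "constant")
  expect_length(f0$model$step_indices, 0)
})
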