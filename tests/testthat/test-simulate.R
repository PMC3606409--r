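test_that("the unwinding fixture matches its documented design", {
  spec <- unwinding_spec()
  expect_s3_class(spec, "step_spec")
  expect_length(spec$step_sizes, 33)
  expect_length(spec$dwell_times, 34)
  expect_equal(spec$sampling_rate, 2500)

  # three downward steps, the rest unit upward
  expect_identical(which(spec$step_sizes < 0), c(12L, 20L, 27L))
  expect_true(all(abs(spec$step_sizes) == 1))

  # transient dwells fixed in milliseconds; dwell j follows step j
  expect_equal(spec$dwell_times[c(1, 6, 7, 29, 30, 31) + 1],
               c(31, 18, 18, 80, 80, 84) / 1000)

  # all remaining dwells drawn from 0.1-2.25 s
  others <- spec$dwell_times[-(c(1, 6, 7, 29, 30, 31) + 1)]
  expect_true(all(others >= 0.1 & others <= 2.25))

  expect_identical(unwinding_spec(seed = 5), unwinding_spec(seed = 5))
  expect_false(identical(unwinding_spec(seed = 5)$dwell_times,
                         unwinding_spec(seed = 6)$dwell_times))
})

test_that("the fixture noise model hits the requested marginal scale", {
  m <- unwinding_noise()
  expect_identical(m$order, 7L)
  expect_equal(m$coefficients, ar7_coefs())
  expect_equal(ar_marginal_sd(m), 0.30, tolerance = 1e-10)

  g <- unwinding_noise(marginal_sd = 0.5, gaussian = TRUE)
  expect_identical(g$order, 0L)
  expect_equal(g$innovation_sd, 0.5)
})

test_that("render_trace reproduces the step function and noise structure", {
  spec <- step_spec(c(0.2, 0.3, 0.1), c(1, -1), sampling_rate = 100)
  sim <- render_trace(spec)
  expect_identical(sim$truth$step_indices, c(20L, 50L))
  expect_identical(sim$truth$n, 60L)
  expect_equal(sim$trace$value, step_signal(sim$truth))
  expect_equal(diff(sim$trace$time)[1], 0.01)

  # Gaussian noise: per-segment sd near the innovation scale
  sg <- render_trace(step_spec(c(4, 4), 1, sampling_rate = 500),
                     noise = ar_model(numeric(0), 0.2), seed = 81)
  seg1 <- sg$trace$value[1:2000]
  expect_equal(sd(seg1), 0.2, tolerance = 0.05)

  # sub-sample dwell is impossible
  expect_error(render_trace(step_spec(c(1e-4, 1), 1, sampling_rate = 100)),
               "at least one sample")
  # noise requires a seed
  expect_error(render_trace(spec, noise = ar_model(0.5, 1)), "seed")
})

test_that("rendered AR(7) noise round-trips through order identification", {
  spec <- step_spec(rep(20, 5), c(1, 1, -1, 1), sampling_rate = 2500)
  m7 <- ar_model(ar7_coefs(), 0.29)
  sim <- render_trace(spec, noise = m7, seed = 82)
  resid <- sim$trace$value - step_signal(sim$truth)
  fit <- fit_ar(resid)
  expect_identical(fit$order, 7L)
  expect_lt(max(abs(fit$coefficients - ar7_coefs())), 0.02)
})

test_that("spec and model representations round-trip", {
  spec <- step_spec(c(0.5, 0.25, 0.75), c(2, -1), sampling_rate = 200)
  sim <- render_trace(spec)
  back <- as_step_spec(sim$truth)
  expect_equal(back$dwell_times, spec$dwell_times, tolerance = 1 / 200)
  expect_equal(back$step_sizes, spec$step_sizes)
  expect_equal(back$sampling_rate, spec$sampling_rate)
})

test_that("replicate_study scores noiseless replicates perfectly", {
  spec <- step_spec(c(0.5, 0.6, 0.5, 0.4), c(1, -1, 2), sampling_rate = 500)
  st <- replicate_study(1, seed = 3, spec = spec, noise = NULL)
  expect_identical(st$n_detected, 3L)
  expect_identical(st$false_positives, 0L)
  expect_identical(st$missed_steps, 0L)
  truth <- attr(st, "truth")
  expect_identical(st$detected[[1]], truth$step_indices)

  # reproducible under the master seed
  st2 <- replicate_study(1, seed = 3, spec = spec, noise = NULL)
  expect_identical(st$detected, st2$detected)
})
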