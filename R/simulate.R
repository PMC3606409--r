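#' Specification of a simulated stepping trajectory
#'
#' Dwell durations (in seconds) and step sizes that define a piecewise-
#' constant mean: `k` steps need `k + 1` dwells (the plateau before the first
#' step plus one after each step).
#'
#' @param dwell_times Positive durations in seconds, length `k + 1`.
#' @param step_sizes Non-zero sizes in signal units, length `k`.
#' @param baseline Starting level (default 0).
#' @param sampling_rate Samples per second (default 2500 Hz).
#' @return An object of class `step_spec`.
#' @export
step_spec <- function(dwell_times, step_sizes, baseline = 0,
                      sampling_rate = 2500) {
  dwell_times <- as.numeric(dwell_times)
  step_sizes <- as.numeric(step_sizes)
  if (length(dwell_times) != length(step_sizes) + 1) {
    abort("Need one more dwell than steps (k + 1 dwells for k steps).")
  }
  if (any(dwell_times <= 0)) abort("Dwell times must be positive.")
  if (any(step_sizes == 0)) abort("Step sizes must be non-zero.")
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  structure(
    list(dwell_times = dwell_times, step_sizes = step_sizes,
         baseline = baseline, sampling_rate = sampling_rate),
    class = "step_spec"
  )
}

#' @export
print.step_spec <- function(x, ...) {
  cat("Step specification:", length(x$step_sizes), "steps,",
      sprintf("%.3f s at %g Hz\n", sum(x$dwell_times), x$sampling_rate))
  invisible(x)
}

# Dwells (plateaus after these steps, 1-based step numbers) that are fixed
# at short, transient durations in the canonical unwinding fixture.
transient_fixture_steps <- function() c(1L, 6L, 7L, 29L, 30L, 31L)
transient_fixture_dwells_s <- function() c(31, 18, 18, 80, 80, 84) / 1000

#' Canonical 33-step mock unwinding fixture
#'
#' A step function resembling a single-molecule RNA-unwinding trace sampled
#' at 2.5 kHz: 33 unit steps, of which three (numbers 12, 20 and 27) are
#' downward, the rest upward. The plateaus immediately following steps 1, 6,
#' 7, 29, 30 and 31 are transient, fixed at 31, 18, 18, 80, 80 and 84 ms; all
#' other dwells (including the initial plateau) are drawn uniformly from
#' 0.1-2.25 s. The positions of the downward steps and the unit step
#' magnitude are package conventions, fixed for reproducibility.
#'
#' @param seed Integer seed controlling the random dwells (default 20130322,
#'   the package's documented fixture seed, so the canonical step function is
#'   the same across sessions).
#' @return A [step_spec()] with 33 steps.
#' @examples
#' spec <- unwinding_spec()
#' length(spec$step_sizes)
#' @export
unwinding_spec <- function(seed = 20130322) {
  k <- 33L
  sizes <- rep(1, k)
  sizes[c(12L, 20L, 27L)] <- -1
  dwells <- withr::with_seed(as.integer(seed),
                             stats::runif(k + 1, 0.1, 2.25))
  dwells[transient_fixture_steps() + 1L] <- transient_fixture_dwells_s()
  step_spec(dwells, sizes, baseline = 0, sampling_rate = 2500)
}

#' AR(7) noise model of the mock unwinding traces
#'
#' The autoregressive noise typical of optical-tweezers unwinding traces:
#' order 7 with coefficients 0.222, 0.072, 0.035, 0.015, 0.016, 0.003 and
#' 0.013. The innovation sd is chosen so the stationary marginal sd of the
#' noise equals `marginal_sd` step units (default 0.30, the package's
#' documented convention for the fixture: steps are clearly visible but
#' overlap the noise). `gaussian = TRUE` returns white noise with the same
#' marginal sd, for like-for-like comparisons.
#'
#' @param marginal_sd Stationary sd of the noise in step units.
#' @param gaussian If `TRUE`, an order-0 (white) model instead.
#' @return An [ar_model()].
#' @export
unwinding_noise <- function(marginal_sd = 0.30, gaussian = FALSE) {
  if (gaussian) return(ar_model(numeric(0), marginal_sd))
  a <- c(0.222, 0.072, 0.035, 0.015, 0.016, 0.003, 0.013)
  unit <- ar_model(a, 1)
  ar_model(a, marginal_sd / ar_marginal_sd(unit))
}

#' Render a trajectory from a step specification
#'
#' Samples the piecewise-constant mean at the specification's sampling rate
#' (each dwell rounded to whole samples) and adds noise drawn from an AR
#' model, or nothing. Returns both the noisy trace and the exact ground-truth
#' step model in sample coordinates.
#'
#' @param spec A [step_spec()].
#' @param noise An [ar_model()], or `NULL` for a noiseless trace.
#' @param seed Integer seed for the noise (required when `noise` is given).
#' @return A list with elements `trace` (tibble: `time`, `value`) and `truth`
#'   (a [step_model()]).
#' @examples
#' sim <- render_trace(step_spec(c(0.2, 0.2), 1, sampling_rate = 100))
#' sim$truth
#' @export
render_trace <- function(spec, noise = NULL, seed = NULL) {
  stopifnot(inherits(spec, "step_spec"))
  seg_len <- round(spec$dwell_times * spec$sampling_rate)
  if (any(seg_len < 1)) {
    abort("Every dwell must span at least one sample at this sampling rate.")
  }
  n <- sum(seg_len)
  levels <- cumsum(c(spec$baseline, spec$step_sizes))
  mu <- rep(levels, seg_len)
  eps <- if (is.null(noise)) {
    numeric(n)
  } else {
    if (is.null(seed)) abort("`seed` is required when noise is simulated.")
    simulate_ar(noise, n, seed = seed)
  }
  truth <- step_model(
    baseline = spec$baseline,
    step_indices = cumsum(seg_len)[seq_along(spec$step_sizes)],
    step_sizes = spec$step_sizes,
    n = n, dt = 1 / spec$sampling_rate
  )
  list(
    trace = new_trace(mu + eps, sampling_rate = spec$sampling_rate),
    truth = truth
  )
}

#' Convert a ground-truth step model back to a specification
#'
#' Inverse of [render_trace()] up to sample rounding: dwell durations are the
#' segment lengths times the sampling interval.
#'
#' @param model A [step_model()].
#' @return A [step_spec()].
#' @export
as_step_spec <- function(model) {
  stopifnot(inherits(model, "step_model"))
  b <- c(0L, model$step_indices, model$n)
  step_spec(diff(b) * model$dt, model$step_sizes, baseline = model$baseline,
            sampling_rate = 1 / model$dt)
}

#' Replicate the simulation study
#'
#' Renders the fixture step function once, adds `n_reps` independent noise
#' realizations, runs [detect_steps()] on each and scores it against the
#' ground truth with [match_steps()]. This reproduces the design of the
#' benchmark: one fixed step function, fresh noise per replicate.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed; the fixture dwell seed and one noise seed per
#'   replicate are derived from it.
#' @param spec Step specification; default the canonical [unwinding_spec()]
#'   with a fixture seed derived from `seed`.
#' @param noise Noise model; default [unwinding_noise()] (AR(7), marginal sd
#'   0.30).
#' @param ... Passed to [detect_steps()] (e.g. `assume_iid = TRUE`).
#' @return A tibble with one row per replicate: `replicate`, `n_detected`,
#'   `false_positives`, `missed_steps`, and list columns `detected`
#'   (0-based indices) and `report` ([match_steps()] result). The ground
#'   truth [step_model()] is attached as attribute `truth`.
#' @export
replicate_study <- function(n_reps, seed, spec = NULL, noise = unwinding_noise(),
                            ...) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1, n_reps + 1))
  if (is.null(spec)) spec <- unwinding_spec(seed = seeds[1])
  noise_seeds <- seeds[-1]
  truth <- NULL
  rows <- purrr::map(seq_len(n_reps), function(r) {
    sim <- render_trace(spec, noise = noise, seed = noise_seeds[r])
    truth <<- sim$truth
    fit <- detect_steps(sim$trace, ...)
    rep_report <- match_steps(sim$truth, fit$model)
    tibble::tibble(
      replicate = r,
      n_detected = length(fit$model$step_indices),
      false_positives = length(rep_report$false_positives),
      missed_steps = length(rep_report$missed_steps),
      detected = list(fit$model$step_indices),
      report = list(rep_report)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  out
}
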