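#' Piecewise-constant step model
#'
#' The mean function of a trace with `k` steps: a baseline `beta0` plus step
#' sizes `beta_j` switched on at 0-based sample indices `t_j` (a step "at
#' index t" means the mean changes between samples `t-1` and `t`; negative
#' sizes are downward steps).
#'
#' @param baseline Mean level of the first segment.
#' @param step_indices Strictly increasing integers in `(0, n)`.
#' @param step_sizes Non-zero sizes, one per step.
#' @param n Series length in samples.
#' @param dt Sampling interval in seconds.
#' @return An object of class `step_model`.
#' @export
step_model <- function(baseline, step_indices, step_sizes, n, dt = 4e-4) {
  step_indices <- as.integer(step_indices)
  step_sizes <- as.numeric(step_sizes)
  n <- as.integer(n)
  if (length(step_indices) != length(step_sizes)) {
    abort("`step_indices` and `step_sizes` must have equal length.")
  }
  if (length(step_indices) > 0) {
    if (any(diff(step_indices) <= 0)) {
      abort("`step_indices` must be strictly increasing.")
    }
    if (step_indices[1] <= 0 || step_indices[length(step_indices)] >= n) {
      abort("`step_indices` must lie strictly inside (0, n).")
    }
    if (any(step_sizes == 0)) abort("Step sizes must be non-zero.")
  }
  structure(
    list(baseline = baseline, step_indices = step_indices,
         step_sizes = step_sizes, n = n, dt = dt),
    class = "step_model"
  )
}

#' @export
print.step_model <- function(x, ...) {
  cat("Step model:", length(x$step_indices), "steps over", x$n, "samples",
      sprintf("(%.4g s at dt = %.3g s)\n", x$n * x$dt, x$dt))
  cat("  baseline:", signif(x$baseline, 5), "\n")
  if (length(x$step_indices) > 0) {
    cat("  step indices:", paste(x$step_indices, collapse = ", "), "\n")
    cat("  step sizes:  ", paste(signif(x$step_sizes, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mean level of a step model at every sample
#'
#' @param model A [step_model()].
#' @return Numeric vector of length `model$n`.
#' @export
step_signal <- function(model) {
  stopifnot(inherits(model, "step_model"))
  b <- c(0L, model$step_indices, model$n)
  levels <- cumsum(c(model$baseline, model$step_sizes))
  rep(levels, diff(b))
}

#' Indicator design matrix for a step regression
#'
#' A column of ones for the baseline plus, for each step at index `t_j`, a
#' 0/1 column equal to 1 for samples `t >= t_j` (Heaviside-type indicator).
#'
#' @param n Series length.
#' @param step_indices Strictly increasing 0-based indices in `(0, n)`.
#' @return An `n x (k+1)` numeric matrix.
#' @export
design_matrix <- function(n, step_indices) {
  step_indices <- as.integer(step_indices)
  if (anyDuplicated(step_indices)) {
    abort("Duplicate step indices are not allowed.")
  }
  if (length(step_indices) > 0 &&
      (any(step_indices <= 0) || any(step_indices >= n))) {
    abort("Step indices must lie strictly inside (0, n).")
  }
  step_indices <- sort(step_indices)
  X <- matrix(0, n, length(step_indices) + 1)
  X[, 1] <- 1
  t0 <- seq_len(n) - 1L
  for (j in seq_along(step_indices)) {
    X[, j + 1] <- as.numeric(t0 >= step_indices[j])
  }
  colnames(X) <- c("baseline",
                   if (length(step_indices) > 0)
                     paste0("step_", step_indices))
  X
}

#' Cochrane-Orcutt whitening filter
#'
#' Applies `z[t] = x[t] - a1 x[t-1] - ... - ap x[t-p]` (the AR polynomial in
#' the backshift operator) and drops the first `p` elements, for which no
#' complete history exists. Filtering a series by its own AR noise model
#' leaves i.i.d. innovations, which is what turns the step regression into an
#' ordinary Gaussian least-squares problem. Order 0 returns the input
#' unchanged.
#'
#' @param x Numeric series (or trace data frame).
#' @param noise An [ar_model()].
#' @return Numeric vector of length `length(x) - order`.
#' @export
co_transform <- function(x, noise) {
  stopifnot(inherits(noise, "ar_model"))
  x <- trace_values(x)
  p <- noise$order
  if (p == 0) return(x)
  n <- length(x)
  if (n <= p) abort("Series shorter than the AR order.")
  z <- x[(p + 1):n]
  for (i in seq_len(p)) {
    z <- z - noise$coefficients[i] * x[(p + 1 - i):(n - i)]
  }
  z
}

#' Akaike and Bayesian information criteria
#'
#' `aic = -2 loglik + 2 p` and `bic = -2 loglik + p log(n)`. For `n > 7` the
#' BIC penalty per parameter exceeds the AIC penalty, so BIC prefers smaller
#' models on all realistic trace lengths.
#'
#' @param loglik Maximised log-likelihood.
#' @param p_total Number of estimated parameters.
#' @param n Number of observations entering the likelihood.
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(loglik, p_total, n) {
  if (any(n < 1) || any(p_total < 1)) {
    abort("`n` and `p_total` must be at least 1.")
  }
  tibble::tibble(
    aic = -2 * loglik + 2 * p_total,
    bic = -2 * loglik + p_total * log(n)
  )
}

# ---- internal GLS engine ---------------------------------------------------
#
# The step regression is fitted in the segment-indicator basis: one disjoint
# 0/1 column per dwell segment instead of cumulative step indicators. The two
# bases span the same column space; segment means map to (baseline, step
# sizes) by first differences. After the Cochrane-Orcutt filter each segment
# column is nonzero only on [s, e + p), so the cross-product matrix is banded
# and both it and X'z are assembled in O(n + k p) without forming the dense
# design. Removing a step merges two segments, i.e. adds two rows/columns of
# the cross-product — an exact O(k) update used along the elimination path.

# Nonzero part of the filtered column for segment [s, e) (0-based, half-open),
# restricted to rows >= p (the dropped initial rows). ca = c(0, cumsum(a)).
segment_column <- function(s, e, n, p, ca) {
  idx <- s:(min(e + p, n) - 1L)
  tt <- idx
  v <- numeric(length(idx))
  inseg <- tt < e
  v[inseg] <- 1 - ca[pmin(p, tt[inseg] - s) + 1L]
  if (any(!inseg)) {
    to <- tt[!inseg]
    v[!inseg] <- -(ca[pmin(p, to - s) + 1L] - ca[to - e + 1L])
  }
  keep <- tt >= p
  list(idx = idx[keep], v = v[keep])
}

# Normal equations of the whitened system. steps: 0-based indices.
# Returns A (k+1 x k+1), bvec, yy = |z_y|^2, np = transformed length.
build_normal_equations <- function(y, steps, a) {
  n <- length(y)
  p <- length(a)
  k <- length(steps)
  b <- c(0L, as.integer(steps), n)
  zy <- if (p == 0) y else {
    z <- y[(p + 1):n]
    for (i in seq_len(p)) z <- z - a[i] * y[(p + 1 - i):(n - i)]
    z
  }
  ca <- c(0, cumsum(a))
  cols <- vector("list", k + 1)
  for (m in seq_len(k + 1)) {
    cols[[m]] <- segment_column(b[m], b[m + 1], n, p, ca)
  }
  A <- matrix(0, k + 1, k + 1)
  bv <- numeric(k + 1)
  for (m in seq_len(k + 1)) {
    cm <- cols[[m]]
    if (length(cm$idx) == 0 || all(cm$v == 0)) {
      abort(paste0("Design is rank deficient: segment ", m,
                   " (samples ", b[m], "-", b[m + 1] - 1,
                   ") vanishes after the whitening transform."))
    }
    bv[m] <- sum(cm$v * zy[cm$idx - p + 1L])
    A[m, m] <- sum(cm$v^2)
    j <- m + 1L
    while (j <= k + 1 && b[j] < b[m + 1] + p) {
      cj <- cols[[j]]
      lo <- max(cm$idx[1], cj$idx[1])
      hi <- min(cm$idx[length(cm$idx)], cj$idx[length(cj$idx)])
      if (hi >= lo) {
        vi <- cm$v[cm$idx >= lo & cm$idx <= hi]
        vj <- cj$v[cj$idx >= lo & cj$idx <= hi]
        A[m, j] <- A[j, m] <- sum(vi * vj)
      }
      j <- j + 1L
    }
  }
  list(A = A, bv = bv, yy = sum(zy^2), np = length(zy), zy = zy, cols = cols,
       boundaries = b, p = p)
}

# Solve the whitened normal equations; return estimates and inference pieces.
# steps are the current 0-based step indices (k = length(steps)).
solve_step_system <- function(A, bv, yy, np, steps, extra_params) {
  k <- length(steps)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    abort(paste0(
      "Design is rank deficient for steps at {",
      paste(steps, collapse = ", "),
      "}; adjacent or duplicate step columns are collinear."
    ))
  }
  mu <- backsolve(R, backsolve(R, bv, transpose = TRUE))
  rss <- max(yy - 2 * sum(bv * mu) + sum(mu * (A %*% mu)), 0)
  # the quadratic form cancels catastrophically when the model interpolates
  # (true RSS 0); below this floor the fit is treated as exact
  if (rss < 1e-10 * yy) rss <- 0
  Ainv <- chol2inv(R)
  beta <- c(mu[1], diff(mu))
  df <- np - (k + 1)
  s2_mle <- rss / np
  s2_unb <- if (df > 0) rss / df else NaN
  var_beta <- numeric(k + 1)
  var_beta[1] <- Ainv[1, 1]
  if (k > 0) {
    dm <- seq_len(k)
    var_beta[dm + 1] <- diag(Ainv)[dm + 1] + diag(Ainv)[dm] -
      2 * Ainv[cbind(dm, dm + 1)]
  }
  se <- sqrt(pmax(var_beta, 0) * s2_unb)
  loglik <- if (rss <= 0 || s2_mle <= 0) Inf else {
    -np / 2 * (log(2 * pi * s2_mle) + 1)
  }
  p_total <- (k + 1) + 1 + extra_params
  ic <- information_criteria(loglik, p_total, np)
  pvals <- rep(NA_real_, k)
  if (k > 0) {
    tstat <- beta[-1] / se[-1]
    pvals <- 2 * pt(-abs(tstat), df)
    # zero residual variance: a step with nonzero size is infinitely
    # significant, a zero-size step carries no evidence
    degenerate <- !is.finite(tstat)
    if (any(degenerate)) {
      pvals[degenerate] <- ifelse(abs(beta[-1][degenerate]) >
                                    sqrt(.Machine$double.eps), 0, 1)
    }
  }
  list(mu = mu, beta = beta, se = se, p_values = pvals, rss = rss,
       sigma2 = s2_mle, loglik = loglik, aic = ic$aic, bic = ic$bic,
       p_total = p_total, df = df)
}

# Full fit for a fixed step set and AR model; returns a step_fit.
fit_step_engine <- function(y, steps, noise, dt, count_ar = TRUE) {
  steps <- as.integer(steps)
  if (anyDuplicated(steps)) {
    abort(paste0("Duplicate step indices: ",
                 paste(unique(steps[duplicated(steps)]), collapse = ", ")))
  }
  steps <- sort(steps)
  n <- length(y)
  if (length(steps) > 0 && (steps[1] <= 0 || steps[length(steps)] >= n)) {
    abort("Step indices must lie strictly inside (0, n).")
  }
  a <- noise$coefficients
  ne <- build_normal_equations(y, steps, a)
  extra <- if (count_ar) noise$order else 0L
  sol <- solve_step_system(ne$A, ne$bv, ne$yy, ne$np, steps, extra)
  # whitened residuals
  fitted_z <- numeric(ne$np)
  for (m in seq_along(ne$cols)) {
    cm <- ne$cols[[m]]
    rows <- cm$idx - ne$p + 1L
    fitted_z[rows] <- fitted_z[rows] + sol$mu[m] * cm$v
  }
  resid_z <- ne$zy - fitted_z
  new_step_fit(
    y = y, steps = steps, sol = sol, noise = noise, dt = dt,
    residuals = resid_z
  )
}

new_step_fit <- function(y, steps, sol, noise, dt, residuals,
                         path = NULL, config = NULL, candidates = NULL) {
  k <- length(steps)
  # unvalidated: an estimated size may be exactly zero mid-elimination
  model <- structure(
    list(baseline = sol$beta[1], step_indices = as.integer(steps),
         step_sizes = if (k > 0) sol$beta[-1] else numeric(0),
         n = length(y), dt = dt),
    class = "step_model"
  )
  structure(
    list(
      model = model,
      standard_errors = sol$se,
      p_values = sol$p_values,
      loglik = sol$loglik,
      aic = sol$aic,
      bic = sol$bic,
      sigma2 = sol$sigma2,
      rss = sol$rss,
      df = sol$df,
      p_total = sol$p_total,
      noise = noise,
      residuals = residuals,
      data = y,
      path = path,
      config = config,
      candidates = candidates
    ),
    class = "step_fit"
  )
}

#' Ordinary least-squares step fit (i.i.d. Gaussian noise)
#'
#' Fits the step regression assuming i.i.d. Gaussian noise; least-squares and
#' maximum-likelihood estimates coincide. With the full indicator basis the
#' estimates are segment means: `beta0` is the mean of the first dwell and
#' each step size the difference of adjacent dwell means.
#'
#' @param trace Trace tibble or numeric vector.
#' @param step_indices 0-based step locations (strictly inside the trace).
#' @return A `step_fit`: estimated [step_model()], standard errors, per-step
#'   t-test p-values, log-likelihood, AIC/BIC, residuals and the noise model
#'   used (order 0 here).
#' @examples
#' y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, sd = 0.1)
#' fit_ols(y, 50)
#' @export
fit_ols <- function(trace, step_indices = integer(0)) {
  y <- trace_values(trace)
  dt <- trace_dt(trace)
  noise <- ar_model(numeric(0), 1)
  fit <- fit_step_engine(y, step_indices, noise, dt, count_ar = FALSE)
  # record the residual scale actually estimated
  fit$noise <- ar_model(numeric(0), max(sqrt(fit$sigma2),
                                        .Machine$double.eps))
  fit
}

#' Generalized least-squares step fit with AR(p) noise
#'
#' Applies the Cochrane-Orcutt filter of `noise` to the response and to every
#' design column, then fits the transformed (whitened) system by ordinary
#' least squares. Likelihood, AIC/BIC, standard errors and t-tests all refer
#' to the transformed system, whose errors are i.i.d. Gaussian when the noise
#' model is correct; the first `p` samples are dropped by the filter, and the
#' likelihood sample size is the transformed length. With an order-0 noise
#' model this reduces exactly to [fit_ols()].
#'
#' @inheritParams fit_ols
#' @param noise An [ar_model()] describing the trace noise.
#' @param count_ar_params Include the AR order in the parameter count used by
#'   AIC/BIC (default `TRUE`; irrelevant for comparisons at fixed noise
#'   model).
#' @return A `step_fit`.
#' @export
fit_gls <- function(trace, step_indices, noise, count_ar_params = TRUE) {
  stopifnot(inherits(noise, "ar_model"))
  y <- trace_values(trace)
  dt <- trace_dt(trace)
  fit_step_engine(y, step_indices, noise, dt,
                  count_ar = count_ar_params && noise$order > 0)
}

#' @export
print.step_fit <- function(x, ...) {
  k <- length(x$model$step_indices)
  cat("GLS step fit:", k, "steps,",
      "AR noise order", x$noise$order, "\n")
  cat(sprintf("  loglik %.2f | AIC %.2f | BIC %.2f | sigma2 %.4g\n",
              x$loglik, x$aic, x$bic, x$sigma2))
  if (k > 0) {
    print(tidy(x), n = min(k, 10))
  } else {
    cat("  baseline-only model, level", signif(x$model$baseline, 5), "\n")
  }
  invisible(x)
}

#' @export
tidy.step_fit <- function(x, ...) {
  k <- length(x$model$step_indices)
  tibble::tibble(
    step_index = x$model$step_indices,
    time_s = x$model$step_indices * x$model$dt,
    size = x$model$step_sizes,
    se = if (k > 0) x$standard_errors[-1] else numeric(0),
    t_p_value = x$p_values
  )
}

#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(
    n = x$model$n,
    n_steps = length(x$model$step_indices),
    baseline = x$model$baseline,
    sigma2 = x$sigma2,
    loglik = x$loglik,
    aic = x$aic,
    bic = x$bic,
    ar_order = x$noise$order
  )
}

#' @export
fitted.step_fit <- function(object, ...) {
  step_signal(object$model)
}

#' @export
residuals.step_fit <- function(object, type = c("whitened", "response"), ...) {
  type <- match.arg(type)
  if (type == "whitened") object$residuals
  else object$data - step_signal(object$model)
}

#' @export
autoplot.step_fit <- function(object, downsample = NULL, ...) {
  n <- object$model$n
  dt <- object$model$dt
  keep <- if (is.null(downsample)) seq_len(n) else {
    seq(1L, n, by = max(1L, as.integer(downsample)))
  }
  df <- tibble::tibble(
    time = (keep - 1) * dt,
    value = object$data[keep],
    fit = step_signal(object$model)[keep]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey60",
                       linewidth = 0.2) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "signal",
                  title = sprintf("Fitted step model (%d steps)",
                                  length(object$model$step_indices)))
}
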