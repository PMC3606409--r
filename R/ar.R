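#' Autoregressive noise model
#'
#' Describes stationary AR(p) noise: each value is a linear combination of the
#' `p` previous values plus an i.i.d. Gaussian innovation,
#' `e[t] = a1 e[t-1] + ... + ap e[t-p] + w[t]`, `w[t] ~ N(0, innovation_sd^2)`.
#' Order 0 is plain i.i.d. Gaussian noise. The model must be second-order
#' stationary: all roots of `1 - a1 z - ... - ap z^p` outside the unit circle.
#'
#' @param coefficients Numeric vector `a1..ap` (may be empty for order 0).
#' @param innovation_sd Positive standard deviation of the innovation.
#' @return An object of class `ar_model` with fields `order`, `coefficients`
#'   and `innovation_sd`.
#' @examples
#' ar_model(c(0.5, 0.3), 1)
#' ar_model(numeric(0), 0.2) # white noise
#' @export
ar_model <- function(coefficients, innovation_sd) {
  coefficients <- as.numeric(coefficients)
  if (anyNA(coefficients)) {
    abort("AR coefficients must be finite numbers.")
  }
  if (!is.numeric(innovation_sd) || length(innovation_sd) != 1 ||
      !is.finite(innovation_sd) || innovation_sd <= 0) {
    abort("`innovation_sd` must be a single positive number.")
  }
  if (length(coefficients) > 0 && !ar_is_stationary(coefficients)) {
    abort(paste0(
      "AR coefficients (", paste(signif(coefficients, 4), collapse = ", "),
      ") do not define a stationary process: ",
      "a root of 1 - a1 z - ... - ap z^p lies on or inside the unit circle."
    ))
  }
  structure(
    list(
      order = length(coefficients),
      coefficients = coefficients,
      innovation_sd = innovation_sd
    ),
    class = "ar_model"
  )
}

ar_is_stationary <- function(coefficients, tol = 1e-8) {
  if (length(coefficients) == 0) return(TRUE)
  all(Mod(polyroot(c(1, -coefficients))) > 1 + tol)
}

#' @export
print.ar_model <- function(x, ...) {
  cat("AR noise model of order", x$order, "\n")
  if (x$order > 0) {
    cat("  coefficients:", paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  }
  cat("  innovation sd:", signif(x$innovation_sd, 4), "\n")
  cat("  marginal sd:  ", signif(ar_marginal_sd(x), 4), "\n")
  invisible(x)
}

#' @export
tidy.ar_model <- function(x, ...) {
  tibble::tibble(
    term = if (x$order > 0) paste0("a", seq_len(x$order)) else character(0),
    estimate = x$coefficients
  )
}

#' @export
glance.ar_model <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    innovation_sd = x$innovation_sd,
    marginal_sd = ar_marginal_sd(x)
  )
}

#' Stationary marginal standard deviation of an AR model
#'
#' The standard deviation of the stationary distribution of the process, i.e.
#' of the noise as seen in a trace. For order 0 this equals the innovation sd;
#' otherwise it follows from the Yule-Walker relation
#' `gamma0 = sigma^2 / (1 - sum(a * rho))` with `rho` the theoretical
#' autocorrelations.
#'
#' @param model An [ar_model()].
#' @return A positive number.
#' @export
ar_marginal_sd <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  if (model$order == 0) return(model$innovation_sd)
  rho <- stats::ARMAacf(ar = model$coefficients, lag.max = model$order)[-1]
  model$innovation_sd / sqrt(1 - sum(model$coefficients * rho))
}

#' Sample autocorrelation or partial autocorrelation of a trace
#'
#' Computes the ACF (biased, divide-by-n estimator, so the sequence is a valid
#' correlation function with value exactly 1 at lag 0) or the PACF
#' (Durbin-Levinson recursion) of a series, together with the pointwise 95%
#' bound under the null hypothesis of no correlation,
#' `qnorm(0.975)/sqrt(n)`. The PACF of AR(p) noise cuts off after lag p, which
#' identifies the order; white noise stays within the bound at every lag.
#'
#' @param x Numeric series, or a trace data frame with a `value` column.
#' @param max_lag Largest lag to compute (positive integer, `< length(x)`).
#' @param type `"acf"` (lags 0..max_lag) or `"pacf"` (lags 1..max_lag).
#' @return A tibble of class `correlogram` with columns `lag`, `value`,
#'   `ci_bound` and an attribute `type`.
#' @examples
#' set.seed(1)
#' x <- simulate_ar(ar_model(0.5, 1), 2000, seed = 1)
#' correlogram(x, 20)
#' correlogram(x, 20, type = "pacf")
#' @export
correlogram <- function(x, max_lag, type = c("acf", "pacf")) {
  type <- match.arg(type)
  x <- trace_values(x)
  n <- length(x)
  if (!is.numeric(max_lag) || length(max_lag) != 1 || max_lag < 1 ||
      max_lag != round(max_lag)) {
    abort("`max_lag` must be a positive integer.")
  }
  if (n <= max_lag) {
    abort("Series must be longer than `max_lag`.")
  }
  check_not_constant(x)
  ci <- qnorm(0.975) / sqrt(n)
  if (type == "acf") {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
    out <- tibble::tibble(lag = 0:max_lag, value = as.numeric(a$acf),
                          ci_bound = ci)
  } else {
    a <- stats::pacf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
    out <- tibble::tibble(lag = 1:max_lag, value = as.numeric(a$acf),
                          ci_bound = ci)
  }
  attr(out, "type") <- type
  class(out) <- c("correlogram", class(out))
  out
}

check_not_constant <- function(x, what = "series") {
  if (length(x) == 0 || !all(is.finite(x))) {
    abort(paste("The", what, "must be non-empty and finite."))
  }
  if (max(x) == min(x)) {
    abort(paste0("Degenerate input: the ", what,
                 " is constant (zero variance)."))
  }
  invisible(x)
}

#' Estimate an AR noise model from a series
#'
#' Identifies the AR order from the PACF cutoff and estimates the coefficients
#' at that order by Yule-Walker. A lag counts as significant when its PACF
#' exceeds the no-correlation null bound; the order is the largest significant
#' lag not exceeding `max_order`, and 0 when no lag is significant (i.i.d.
#' noise). Because `max_order` lags are scanned simultaneously, the default
#' bound is Bonferroni-adjusted (`qnorm(1 - alpha/2/max_order)/sqrt(n)`);
#' with the unadjusted pointwise bound (`adjust = "none"`) the largest
#' "significant" lag is an isolated false positive with high probability once
#' n is large, inflating the order. `method = "aic"` instead delegates order
#' choice to AIC as implemented in [stats::ar.yw()].
#'
#' @param x Numeric series (or trace data frame); typically fit residuals.
#' @param max_order Largest order considered (default 20).
#' @param method `"pacf"` (cutoff rule, default) or `"aic"`.
#' @param alpha Significance level for the PACF cutoff (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"none"` multiplicity handling.
#' @return An [ar_model()]. Order 0 carries `innovation_sd = sd(x)`.
#' @examples
#' x <- simulate_ar(ar_model(c(0.5, 0.3), 1), 5000, seed = 42)
#' fit_ar(x)
#' @export
fit_ar <- function(x, max_order = 20, method = c("pacf", "aic"),
                   alpha = 0.05, adjust = c("bonferroni", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  x <- trace_values(x)
  check_not_constant(x)
  n <- length(x)
  if (n <= 10 * max_order) {
    max_order <- max(1L, floor((n - 1) / 10))
  }
  if (method == "aic") {
    fit <- stats::ar.yw(x, aic = TRUE, order.max = max_order, demean = TRUE)
    if (fit$order == 0) {
      return(ar_model(numeric(0), sd(x)))
    }
    return(ar_model(fit$ar, sqrt(fit$var.pred)))
  }
  pac <- as.numeric(stats::pacf(x, lag.max = max_order, plot = FALSE)$acf)
  m <- if (adjust == "bonferroni") max_order else 1
  bound <- qnorm(1 - alpha / 2 / m) / sqrt(n)
  sig <- which(abs(pac) > bound)
  if (length(sig) == 0) {
    return(ar_model(numeric(0), sd(x)))
  }
  order <- max(sig)
  fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  ar_model(fit$ar, sqrt(fit$var.pred))
}

#' Simulate a stationary AR(p) realization
#'
#' Draws a zero-mean realization of the model, discarding `burn_in` initial
#' samples so the output is (to numerical accuracy) a draw from the stationary
#' distribution. Reproducible: the same `seed` gives the same series, and the
#' caller's RNG state is left untouched.
#'
#' @param model An [ar_model()].
#' @param n Number of samples to return.
#' @param seed Integer seed (required; no hidden global state is used).
#' @param burn_in Initial samples to discard; default `max(500, 50 * order)`.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_ar(ar_model(0.9, 1), 1000, seed = 7)
#' var(x) # near 1 / (1 - 0.81)
#' @export
simulate_ar <- function(model, n, seed,
                        burn_in = max(500, 50 * model$order)) {
  stopifnot(inherits(model, "ar_model"))
  if (missing(seed)) abort("`seed` is required for simulate_ar().")
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive integer.")
  }
  if (burn_in < 10 * model$order) {
    abort("`burn_in` must be at least 10 times the AR order.")
  }
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    if (model$order == 0) {
      stats::rnorm(n, 0, model$innovation_sd)
    } else {
      as.numeric(stats::arima.sim(
        model = list(ar = model$coefficients),
        n = n,
        n.start = max(burn_in, model$order + 1),
        sd = model$innovation_sd
      ))
    }
  })
}

#' @export
autoplot.correlogram <- function(object, ...) {
  type <- toupper(attr(object, "type"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * object$ci_bound[1],
      linetype = "dashed", colour = "blue"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::labs(x = "lag", y = type,
                  title = paste(type, "with 95% no-correlation bounds"))
}
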