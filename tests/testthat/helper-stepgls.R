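# Shared fixtures for the test suite. All data are generated in code.

# AR(7) coefficients typical of optical-tweezers unwinding traces
ar7_coefs <- function() c(0.222, 0.072, 0.035, 0.015, 0.016, 0.003, 0.013)

# a small noiseless staircase trace with known steps
staircase <- function(seg_len = c(60, 50, 70), sizes = c(2, -1),
                      baseline = 0) {
  rep(cumsum(c(baseline, sizes)), seg_len)
}

# independent PACF oracle: partial autocorrelation at lag h is the last
# coefficient of the regression of x_t on x_{t-1}, ..., x_{t-h}
brute_pacf <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  vapply(seq_len(max_lag), function(h) {
    Y <- x[(h + 1):n]
    X <- sapply(seq_len(h), function(i) x[(h + 1 - i):(n - i)])
    unname(coef(lm(Y ~ X))[h + 1])
  }, numeric(1))
}

# independent eta oracle: direct evaluation of the definition with
# stats::quantile
brute_eta <- function(y, i, w) {
  n <- length(y)
  we <- min(w, i, n - 1 - i)
  left <- y[(i - we + 1):(i + 1)]
  right <- y[(i + 1):(i + we + 1)]
  rng <- max(left, right) - min(left, right)
  if (rng == 0) return(0)
  ql <- quantile(left, c(0.25, 0.5, 0.75), names = FALSE)
  qr <- quantile(right, c(0.25, 0.5, 0.75), names = FALSE)
  mean((ql - qr)^2) / rng^2
}

# dense least-squares oracle for the whitened step regression
lm_step_oracle <- function(y, steps, noise = NULL) {
  n <- length(y)
  X <- design_matrix(n, steps)
  if (!is.null(noise) && noise$order > 0) {
    y <- co_transform(y, noise)
    X <- apply(X, 2, co_transform, noise = noise)
  }
  lm(y ~ X - 1)
}
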