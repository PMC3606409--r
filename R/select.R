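#' Backward elimination over a candidate step set
#'
#' Implements the model-selection loop of the GLS framework as an iterated
#' feasible-GLS (Cochrane-Orcutt style) procedure. Each elimination pass
#' fits all remaining candidates, repeatedly removes the step with the
#' largest t-test p-value (ties broken towards the smallest index), and
#' keeps the model with the lowest information criterion along the path
#' (ties towards fewer steps). The first pass runs under the i.i.d. Gaussian
#' assumption, as when the noise structure is still unknown; the residuals
#' of its selected model are then examined for autocorrelation with
#' [fit_ar()]. If none is found (or `assume_iid` is set) that fit is
#' returned. Otherwise the elimination is repeated from the full candidate
#' set with every fit whitened by the estimated AR model ([fit_gls()]), the
#' noise is re-estimated from the new selection's residuals, and so on until
#' the selected step set repeats (almost always 2-3 passes) or
#' `max_iterations` is reached.
#'
#' Two details matter for stability. The noise is estimated from the
#' residuals of a *selected* model, never from the saturated all-candidates
#' fit: with a dense candidate set the saturated fit absorbs most of the
#' noise into tiny segments, leaving residuals whose spurious
#' anticorrelation corrupts the AR estimate. And within each pass the AR
#' model is held fixed, so all criteria on that path are mutually
#' comparable; the normal equations are updated by exact segment merges.
#' `reestimate_ar = TRUE` instead re-estimates the noise from the residuals
#' of every intermediate model (slower, and its per-round criteria are not
#' mutually comparable).
#'
#' @param trace Trace tibble or numeric vector.
#' @param candidates A `candidate_set` from [build_superset()], or an integer
#'   vector of 0-based candidate indices. Empty input returns the
#'   baseline-only fit.
#' @param assume_iid Force order-0 noise (the "ignoring correlation"
#'   procedure); OLS standard errors are then used throughout.
#' @param max_ar_order Largest AR order considered for the residual noise
#'   (default 20).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param reestimate_ar Re-estimate the AR model at every elimination round.
#' @param max_iterations Cap on feasible-GLS iterations (default 10).
#' @return A `step_fit` whose `path` element is a tibble with one row per
#'   elimination round of the final pass (`round`, `n_steps`, `loglik`,
#'   `aic`, `bic`, `removed_index`, `removed_p`) and whose `config` echoes
#'   the settings.
#' @export
backward_select <- function(trace, candidates, assume_iid = FALSE,
                            max_ar_order = 20, criterion = c("bic", "aic"),
                            reestimate_ar = FALSE, max_iterations = 10) {
  criterion <- match.arg(criterion)
  y <- trace_values(trace)
  dt <- trace_dt(trace)
  n <- length(y)
  cand <- if (is.data.frame(candidates)) candidates$index else candidates
  cand <- sort(unique(as.integer(cand)))
  cand <- cand[cand > 0 & cand < n]
  iid <- ar_model(numeric(0), 1)
  config <- list(assume_iid = assume_iid, max_ar_order = max_ar_order,
                 criterion = criterion, n_candidates = length(cand),
                 reestimate_ar = reestimate_ar)

  if (length(cand) == 0) {
    base <- fit_step_engine(y, integer(0), iid, dt, count_ar = FALSE)
    noise <- residual_noise(y - step_signal(base$model), y, assume_iid,
                            max_ar_order)
    fit <- fit_step_engine(y, integer(0), noise, dt,
                           count_ar = noise$order > 0)
    fit$config <- config
    fit$path <- tibble::tibble(
      round = 1L, n_steps = 0L, loglik = fit$loglik, aic = fit$aic,
      bic = fit$bic, removed_index = NA_integer_, removed_p = NA_real_
    )
    return(fit)
  }

  if (reestimate_ar && !assume_iid) {
    return(backward_select_reestimate(y, cand, dt, max_ar_order, criterion,
                                      config))
  }

  # first pass: eliminate under the i.i.d. assumption, as when the noise
  # structure is still unknown
  s <- run_elimination(y, cand, iid, dt, criterion)
  seen <- list(s$best_steps)
  noise <- iid
  # iterate the feasible-GLS loop: noise from the residuals of the currently
  # selected model, then a fresh whitened elimination, until the selected
  # step set repeats (fixed point or cycle)
  for (it in seq_len(max_iterations)) {
    fit_cur <- fit_step_engine(y, s$best_steps, iid, dt, count_ar = FALSE)
    noise <- residual_noise(y - step_signal(fit_cur$model), y, assume_iid,
                            max_ar_order)
    if (noise$order == 0) {
      fit_cur$noise <- ar_model(numeric(0), max(sqrt(fit_cur$sigma2),
                                                .Machine$double.eps))
      fit_cur$path <- s$path
      fit_cur$config <- config
      return(fit_cur)
    }
    s_new <- run_elimination(y, cand, noise, dt, criterion)
    converged <- any(vapply(seen, identical, logical(1), s_new$best_steps))
    s <- s_new
    if (converged) break
    seen <- c(seen, list(s_new$best_steps))
  }
  fit <- fit_step_engine(y, s$best_steps, noise, dt, count_ar = TRUE)
  fit$path <- s$path
  fit$config <- config
  fit
}

# AR model of the noise as seen in model residuals; order 0 for (numerically)
# noiseless residuals or when the i.i.d. assumption is imposed
residual_noise <- function(resid, y, assume_iid, max_ar_order) {
  if (assume_iid || sd(resid) < 1e-10 * max(sd(y), 1)) {
    ar_model(numeric(0), max(sd(resid), .Machine$double.eps))
  } else {
    fit_ar(resid, max_order = max_ar_order)
  }
}

# one backward-elimination pass at a fixed noise model, using exact row/col
# merges of the whitened normal equations along the path
run_elimination <- function(y, cand, noise, dt, criterion) {
  ne <- build_normal_equations(y, cand, noise$coefficients)
  A <- ne$A
  bv <- ne$bv
  steps <- cand
  extra <- if (noise$order > 0) noise$order else 0L
  rounds <- vector("list", length(cand) + 1L)
  for (r in seq_along(rounds)) {
    sol <- solve_step_system(A, bv, ne$yy, ne$np, steps, extra)
    kk <- length(steps)
    drop_at <- if (kk > 0) pick_removal(sol$p_values) else NA_integer_
    rounds[[r]] <- tibble::tibble(
      round = r, n_steps = kk, loglik = sol$loglik, aic = sol$aic,
      bic = sol$bic,
      removed_index = if (kk > 0) steps[drop_at] else NA_integer_,
      removed_p = if (kk > 0) sol$p_values[drop_at] else NA_real_
    )
    if (kk == 0) break
    # removing step j merges segments j and j+1: exact row/col merge
    m <- drop_at
    A[m, ] <- A[m, ] + A[m + 1, ]
    A[, m] <- A[, m] + A[, m + 1]
    A <- A[-(m + 1), -(m + 1), drop = FALSE]
    bv[m] <- bv[m] + bv[m + 1]
    bv <- bv[-(m + 1)]
    steps <- steps[-m]
  }
  path <- dplyr::bind_rows(rounds)
  best_round <- pick_best_round(path, criterion)
  list(path = path, best_steps = steps_at_round(cand, path, best_round))
}

# per-round AR re-estimation variant (exposed as an option)
backward_select_reestimate <- function(y, cand, dt, max_ar_order, criterion,
                                       config) {
  iid <- ar_model(numeric(0), 1)
  path_fit <- function(steps) {
    r <- y - step_signal(fit_step_engine(y, steps, iid, dt)$model)
    ns <- residual_noise(r, y, FALSE, max_ar_order)
    fit_step_engine(y, steps, ns, dt, count_ar = ns$order > 0)
  }
  steps <- cand
  rounds <- list()
  repeat {
    f <- path_fit(steps)
    kk <- length(steps)
    drop_at <- if (kk > 0) pick_removal(f$p_values) else NA_integer_
    rounds[[length(rounds) + 1]] <- tibble::tibble(
      round = length(rounds) + 1L, n_steps = kk, loglik = f$loglik,
      aic = f$aic, bic = f$bic,
      removed_index = if (kk > 0) steps[drop_at] else NA_integer_,
      removed_p = if (kk > 0) f$p_values[drop_at] else NA_real_
    )
    if (kk == 0) break
    steps <- steps[-drop_at]
  }
  path <- dplyr::bind_rows(rounds)
  best_round <- pick_best_round(path, criterion)
  fit <- path_fit(steps_at_round(cand, path, best_round))
  fit$path <- path
  fit$config <- config
  fit
}

# index of the step to remove: largest p-value, ties toward smallest index
# (steps are kept sorted, so the first maximum is the smallest index)
pick_removal <- function(pvals) {
  pv <- ifelse(is.na(pvals), 1, pvals)
  which.max(pv)
}

# lowest criterion; ties toward fewer steps (later round)
pick_best_round <- function(path, criterion) {
  crit <- path[[criterion]]
  best <- which(crit == min(crit))
  best[length(best)]
}

# reconstruct the step set present at a given round of the path
steps_at_round <- function(cand, path, round) {
  removed <- path$removed_index[seq_len(round - 1)]
  setdiff(cand, removed[!is.na(removed)])
}

#' Detect steps in a trace
#'
#' End-to-end pipeline: build the superset of plausible step locations with
#' the multi-window quantile-contrast scan ([build_superset()]), then select
#' the final model by GLS backward elimination ([backward_select()]). With
#' `assume_iid = TRUE` the noise is treated as Gaussian white noise even if it
#' is autocorrelated, which on correlated traces systematically inflates the
#' detected step count.
#'
#' @inheritParams backward_select
#' @param windows Window half-widths for the candidate scan; default
#'   [eta_windows()].
#' @param threshold_quantile Per-window eta cutoff quantile (default 0.90).
#' @param merge_tol Candidate merge tolerance in samples (default 5).
#' @param candidate_cap Keep at most this many candidates, ranked by eta
#'   (default 500; a computational guard).
#' @return A `step_fit`; its `candidates` element stores the candidate set.
#' @examples
#' sim <- render_trace(
#'   step_spec(c(0.4, 0.4, 0.4), c(1, -1), sampling_rate = 500),
#'   noise = ar_model(numeric(0), 0.2), seed = 1
#' )
#' fit <- detect_steps(sim$trace)
#' tidy(fit)
#' @export
detect_steps <- function(trace, windows = NULL, threshold_quantile = 0.9,
                         merge_tol = 5, candidate_cap = 500,
                         assume_iid = FALSE, max_ar_order = 20,
                         criterion = c("bic", "aic"),
                         reestimate_ar = FALSE) {
  criterion <- match.arg(criterion)
  y <- trace_values(trace)
  dt <- trace_dt(trace)
  if (length(y) < 100) {
    abort("Trace too short: step detection needs at least 100 samples.")
  }
  if (max(y) == min(y)) {
    warn("Trace is constant; returning a baseline-only model.")
    fit <- fit_step_engine(y, integer(0), ar_model(numeric(0), 1), dt,
                           count_ar = FALSE)
    fit$config <- list(constant_trace = TRUE)
    return(fit)
  }
  cand <- build_superset(y, windows = windows,
                         threshold_quantile = threshold_quantile,
                         merge_tol = merge_tol)
  if (nrow(cand) > candidate_cap) {
    keep <- order(cand$eta, decreasing = TRUE)[seq_len(candidate_cap)]
    cand <- cand[sort(keep), ]
  }
  fit <- backward_select(y, cand, assume_iid = assume_iid,
                         max_ar_order = max_ar_order, criterion = criterion,
                         reestimate_ar = reestimate_ar)
  fit$model$dt <- dt
  fit$candidates <- cand
  fit$config <- c(fit$config,
                  list(threshold_quantile = threshold_quantile,
                       merge_tol = merge_tol, candidate_cap = candidate_cap))
  fit
}
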