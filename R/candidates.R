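#' Quantile-contrast step statistic at a single index
#'
#' For a window of half-width `w` centred on sample `i` (0-based), compare the
#' left half `y[i-w..i]` and right half `y[i..i+w]` (the centre sample belongs
#' to both) through their 0.25/0.5/0.75 quantiles: eta is the mean squared
#' quartile difference divided by the squared range of the full window, so
#' `0 <= eta <= 1`. A window whose halves have identical distributions scores
#' near 0; a clean step scores near 1. Near the series ends the half-width
#' shrinks to `min(w, i, n-1-i)`; a zero-range (constant) window scores 0 by
#' convention. Quantiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7) — the value of eta depends on this choice,
#' which is fixed throughout the package.
#'
#' @param trace Trace tibble or numeric vector.
#' @param i 0-based sample index.
#' @param w Window half-width (samples).
#' @return Eta in `[0, 1]`.
#' @examples
#' eta_at(c(0, 0, 0, 0, 0, 1, 1, 1, 1), 4, 4)
#' @export
eta_at <- function(trace, i, w) {
  y <- trace_values(trace)
  n <- length(y)
  if (i < 0 || i >= n) abort("`i` must be a 0-based index into the trace.")
  we <- min(w, i, n - 1 - i)
  il <- i + 1
  left <- y[(il - we):il]
  right <- y[il:(il + we)]
  rng <- max(left, right) - min(left, right)
  if (rng == 0) return(0)
  ql <- quantile(left, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qr <- quantile(right, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mean((ql - qr)^2) / rng^2
}

#' Eta profile over a whole trace
#'
#' Evaluates [eta_at()] at every sample for one window half-width. Peaks of
#' the profile mark plausible step locations.
#'
#' @inheritParams eta_at
#' @param w Window half-width (samples).
#' @return A tibble with columns `index` (0-based) and `eta`, attribute
#'   `window`.
#' @export
eta_profile <- function(trace, w) {
  y <- trace_values(trace)
  if (!is.numeric(w) || length(w) != 1 || w < 2 || w != round(w)) {
    abort("`w` must be an integer half-width >= 2.")
  }
  out <- tibble::tibble(
    index = seq_along(y) - 1L,
    eta = as.numeric(eta_scan_cpp(y, as.integer(w)))
  )
  attr(out, "window") <- as.integer(w)
  out
}

#' Default window set for the candidate scan
#'
#' Half-widths 10 to 100 in steps of 10 and 100 to 1000 in steps of 25,
#' truncated to windows smaller than half the trace length so both window
#' halves fit informative data.
#'
#' @param n Trace length in samples.
#' @return Integer vector of half-widths.
#' @export
eta_windows <- function(n) {
  w <- unique(c(seq(10L, 100L, by = 10L), seq(100L, 1000L, by = 25L)))
  w <- w[w < n / 2]
  if (length(w) == 0) w <- max(2L, floor(n / 4))
  as.integer(w)
}

# Local maxima of v within a +/- h neighbourhood, restricted to `keep`
# (1-based indices). A sample qualifies when it attains its neighbourhood
# maximum; runs of consecutive tied qualifiers (eta plateaus, which occur on
# noiseless steps) collapse to their middle sample. With noise, ties are
# absent and this is the usual strict local maximum.
local_maxima <- function(v, h, keep) {
  n <- length(v)
  ok <- vapply(keep, function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    v[i] >= max(v[lo:hi])
  }, logical(1))
  q <- keep[ok]
  if (length(q) <= 1) return(q)
  run <- cumsum(c(1L, as.integer(diff(q) > 1L)))
  # middle of the run, rounding right: a step "at index t" changes the mean
  # between samples t-1 and t, so the boundary sits right of centre
  vapply(split(q, run), function(ix) ix[floor(length(ix) / 2) + 1L],
         integer(1), USE.NAMES = FALSE)
}

#' Superset of plausible step locations
#'
#' Scans the eta profile over a family of window half-widths; for each window,
#' samples whose eta value is a strict local maximum (within a horizon of
#' `max(2, w/10)` samples) and exceeds that window's `threshold_quantile` of
#' eta are nominated. The union over windows is taken, nominations closer than
#' `merge_tol` samples are collapsed to the one with the largest eta, and the
#' first and last samples are excluded (a step there is unidentifiable).
#'
#' @inheritParams eta_at
#' @param windows Integer vector of half-widths; default [eta_windows()].
#' @param threshold_quantile Per-window eta quantile cutoff in (0,1);
#'   default 0.90.
#' @param merge_tol Nominations closer than this many samples are merged
#'   (default 5).
#' @return A tibble of class `candidate_set`, one row per candidate, with
#'   columns `index` (0-based, strictly increasing), `eta` (largest nominating
#'   value), `window` (the half-width that produced it) and `n_windows`
#'   (how many windows nominated a sample merged into this candidate).
#' @examples
#' tr <- c(rep(0, 200), rep(1, 200))
#' build_superset(tr, windows = 50)
#' @export
build_superset <- function(trace, windows = NULL,
                           threshold_quantile = 0.9, merge_tol = 5) {
  y <- trace_values(trace)
  n <- length(y)
  if (is.null(windows)) windows <- eta_windows(n)
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) == 0) abort("`windows` must be non-empty.")
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    abort("`threshold_quantile` must be in (0, 1).")
  }
  empty <- tibble::tibble(index = integer(0), eta = numeric(0),
                          window = integer(0), n_windows = integer(0))
  if (max(y) == min(y)) {
    out <- empty
    attr(out, "threshold_quantile") <- threshold_quantile
    class(out) <- c("candidate_set", class(out))
    return(out)
  }
  noms <- purrr::map(windows, function(w) {
    v <- as.numeric(eta_scan_cpp(y, w))
    cut <- quantile(v, threshold_quantile, names = FALSE, type = 7)
    above <- which(v > cut & v > 0)
    above <- above[above > 1 & above < n] # drop first/last sample
    if (length(above) == 0) return(NULL)
    h <- max(2L, as.integer(round(w / 10)))
    peaks <- local_maxima(v, h, above)
    if (length(peaks) == 0) return(NULL)
    tibble::tibble(index = peaks - 1L, eta = v[peaks], window = w)
  })
  noms <- dplyr::bind_rows(noms)
  if (nrow(noms) == 0) {
    out <- empty
  } else {
    # aggregate nominations per sample; eta ties (exact plateaus on clean
    # steps) break towards the sample nominated by the most windows
    per_index <- noms |>
      dplyr::group_by(.data$index) |>
      dplyr::summarise(
        window = .data$window[which.max(.data$eta)],
        n_nom = dplyr::n(),
        eta = max(.data$eta),
        .groups = "drop"
      )
    # greedy merge, strongest first: a nomination survives only if no
    # already-accepted candidate lies within merge_tol samples, so merging
    # cannot chain across a run of closely spaced nominations
    all_noms <- noms
    noms <- dplyr::arrange(per_index, dplyr::desc(.data$eta),
                           dplyr::desc(.data$n_nom), .data$index)
    occupied <- logical(n)
    keep <- logical(nrow(noms))
    for (r in seq_len(nrow(noms))) {
      i <- noms$index[r] + 1L
      lo <- max(1L, i - (merge_tol - 1L))
      hi <- min(n, i + (merge_tol - 1L))
      if (!any(occupied[lo:hi])) {
        occupied[i] <- TRUE
        keep[r] <- TRUE
      }
    }
    kept <- noms[keep, ]
    # per surviving candidate, the number of nominations within merge_tol
    si <- sort(all_noms$index)
    kept$n_windows <- findInterval(kept$index + (merge_tol - 1L), si) -
      findInterval(kept$index - merge_tol, si)
    out <- dplyr::arrange(kept, .data$index) |>
      dplyr::select("index", "eta", "window", "n_windows")
  }
  attr(out, "threshold_quantile") <- threshold_quantile
  class(out) <- c("candidate_set", class(out))
  out
}
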