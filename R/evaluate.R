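#' Signed step-location deviation as a percentage of the adjacent dwell
#'
#' The deviation of a detected step from its true location, normalized by the
#' true dwell on the side of the error: detections to the left are divided by
#' the left dwell, detections to the right by the right dwell, and an exact
#' hit is 0%. E.g. with a left dwell of 50 samples, a detection 10 samples
#' left scores -20%; with a right dwell of 100, a detection 30 samples right
#' scores +30%.
#'
#' @param true_index,detected_index 0-based sample indices (vectorized).
#' @param left_dwell,right_dwell True dwell lengths adjacent to the step, in
#'   samples (positive).
#' @return Signed percentage(s).
#' @examples
#' deviation_percent(1000, 990, 50, 100)  # -20
#' deviation_percent(1000, 1030, 50, 100) # +30
#' @export
deviation_percent <- function(true_index, detected_index,
                              left_dwell, right_dwell) {
  if (any(left_dwell <= 0) || any(right_dwell <= 0)) {
    abort("Dwell lengths must be positive.")
  }
  d <- detected_index - true_index
  ifelse(d < 0, d / left_dwell, d / right_dwell) * 100
}

#' Match detected steps to ground truth
#'
#' Greedy nearest-neighbour matching in increasing-distance order: candidate
#' pairs are accepted only when the detected step lies within 50% of the
#' shorter of the true step's two adjacent dwells (so a detection can never
#' be attributed across a full neighbouring dwell), and each true and each
#' detected step is used at most once. Distance ties are resolved towards the
#' earlier true step. Unmatched detections are false positives; unmatched
#' true steps are missed steps (the benchmark tables call these "true
#' negatives").
#'
#' @param truth A [step_model()] (ground truth).
#' @param detected A [step_model()], a `step_fit`, or an integer vector of
#'   0-based detected indices.
#' @param radius_factor Acceptance radius as a fraction of the shorter
#'   adjacent true dwell (default 0.5).
#' @return An object of class `match_report`: list with `pairs` (tibble:
#'   `true_index`, `detected_index`, `deviation_pct`), `false_positives`,
#'   `missed_steps` (integer index vectors), `n_true`, `n_detected`.
#' @export
match_steps <- function(truth, detected, radius_factor = 0.5) {
  stopifnot(inherits(truth, "step_model"))
  if (inherits(detected, "step_fit")) detected <- detected$model
  det <- if (inherits(detected, "step_model")) detected$step_indices
         else sort(as.integer(detected))
  tr <- truth$step_indices
  b <- c(0L, tr, truth$n)
  left <- diff(b)[seq_along(tr)]
  right <- diff(b)[seq_along(tr) + 1L]
  radius <- radius_factor * pmin(left, right)

  if (length(tr) == 0 || length(det) == 0) {
    out <- list(
      pairs = tibble::tibble(true_index = integer(0),
                             detected_index = integer(0),
                             deviation_pct = numeric(0)),
      false_positives = det,
      missed_steps = tr,
      n_true = length(tr), n_detected = length(det)
    )
    class(out) <- "match_report"
    return(out)
  }

  dist <- abs(outer(tr, det, `-`))
  ok <- which(dist <= radius, arr.ind = TRUE)
  if (nrow(ok) > 0) {
    ord <- order(dist[ok], ok[, 1], ok[, 2])
    ok <- ok[ord, , drop = FALSE]
  }
  used_t <- logical(length(tr))
  used_d <- logical(length(det))
  ti <- integer(0); di <- integer(0)
  for (r in seq_len(nrow(ok))) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE; used_d[j] <- TRUE
      ti <- c(ti, i); di <- c(di, j)
    }
  }
  o <- order(ti)
  ti <- ti[o]; di <- di[o]
  out <- list(
    pairs = tibble::tibble(
      true_index = tr[ti],
      detected_index = det[di],
      deviation_pct = deviation_percent(tr[ti], det[di], left[ti], right[ti])
    ),
    false_positives = det[!used_d],
    missed_steps = tr[!used_t],
    n_true = length(tr),
    n_detected = length(det)
  )
  class(out) <- "match_report"
  out
}

#' @export
print.match_report <- function(x, ...) {
  cat("Step match report:", nrow(x$pairs), "matched,",
      length(x$false_positives), "false positives,",
      length(x$missed_steps), "missed steps (\"true negatives\")\n")
  invisible(x)
}

#' @export
tidy.match_report <- function(x, ...) x$pairs

#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(
    n_true = x$n_true,
    n_detected = x$n_detected,
    matched = nrow(x$pairs),
    false_positives = length(x$false_positives),
    missed_steps = length(x$missed_steps)
  )
}

#' Per-step detection efficiency across replicates
#'
#' For each true step, the fraction of replicate analyses in which it was
#' matched to a detection.
#'
#' @param reports List of [match_steps()] reports (or a [replicate_study()]
#'   tibble, whose `report` column is used).
#' @param truth The ground-truth [step_model()]; taken from the study's
#'   `truth` attribute when `reports` is a study tibble.
#' @return A tibble with columns `step` (1-based step number), `index`
#'   (0-based sample index) and `fraction`.
#' @export
aggregate_efficiency <- function(reports, truth = NULL) {
  if (is.data.frame(reports)) {
    if (is.null(truth)) truth <- attr(reports, "truth")
    reports <- reports$report
  }
  if (length(reports) < 1) abort("Need at least one match report.")
  stopifnot(inherits(truth, "step_model"))
  tr <- truth$step_indices
  hits <- numeric(length(tr))
  for (rep in reports) {
    hits <- hits + as.numeric(tr %in% rep$pairs$true_index)
  }
  tibble::tibble(
    step = seq_along(tr),
    index = tr,
    fraction = hits / length(reports)
  )
}

#' Six-number summary rows for replicate counts
#'
#' Min, quartiles, median, mean and max of a per-replicate count — the layout
#' used by the benchmark's summary tables for step counts, false positives
#' and missed steps.
#'
#' @param x Numeric vector (e.g. detected step counts per replicate).
#' @param label Row label.
#' @return One-row tibble: `label`, `min`, `q1`, `median`, `mean`, `q3`,
#'   `max`.
#' @export
summary_row <- function(x, label = "steps") {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    label = label, min = min(x), q1 = q[1], median = q[2],
    mean = mean(x), q3 = q[3], max = max(x)
  )
}
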