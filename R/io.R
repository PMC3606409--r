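#' Build a trace tibble from sampled values
#'
#' A trace is an ordinary tibble with columns `time` (seconds) and `value`
#' (signal units, e.g. nm or bp), uniformly sampled. Most stepgls functions
#' accept either such a tibble or a bare numeric vector.
#'
#' @param values Numeric vector of samples.
#' @param sampling_rate Samples per second (default 2500 Hz, i.e. dt = 0.4 ms).
#' @param units_label Free-text unit label stored as an attribute.
#' @return A tibble with columns `time` and `value`.
#' @examples
#' new_trace(rnorm(10), sampling_rate = 2500)
#' @export
new_trace <- function(values, sampling_rate = 2500, units_label = "signal") {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values)) {
    abort("Trace values must be non-empty and free of missing values.")
  }
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  out <- tibble::tibble(
    time = (seq_along(values) - 1) / sampling_rate,
    value = values
  )
  attr(out, "units_label") <- units_label
  out
}

# Accept a numeric vector, a trace tibble (value column), or anything coercible.
trace_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      abort("Trace data frames must have a `value` column.")
    }
    v <- as.numeric(x$value)
  } else {
    v <- as.numeric(x)
  }
  if (anyNA(v)) abort("Trace contains missing or non-numeric values.")
  v
}

# Sampling interval in seconds; falls back to `default` for bare vectors.
trace_dt <- function(x, default = 4e-4) {
  if (is.data.frame(x) && "time" %in% names(x) && nrow(x) >= 2) {
    dt <- diff(as.numeric(x$time))
    return(stats::median(dt))
  }
  default
}

#' Read a trace from delimited text
#'
#' Accepts one-column files (values only; `sampling_rate` is then required) or
#' two-column files (time in seconds, value). Two-column input must be
#' uniformly sampled. A header line is detected automatically.
#'
#' @param path File path.
#' @param sampling_rate Samples per second; required for one-column files,
#'   cross-checked against timestamps for two-column files when given.
#' @param delim Field delimiter (default tab).
#' @param rtol Relative tolerance on timestamp uniformity (default 1e-6).
#' @return A trace tibble (`time`, `value`).
#' @export
read_trace <- function(path, sampling_rate = NULL, delim = "\t", rtol = 1e-6) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (file.size(path) == 0) abort(paste0("Empty trace file: ", path))
  first <- readLines(path, n = 1)
  fields <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(fields)))
  dat <- tryCatch(
    utils::read.delim(path, sep = delim, header = has_header,
                      strip.white = TRUE),
    error = function(e) abort(paste0("Could not parse trace file: ",
                                     conditionMessage(e)))
  )
  if (nrow(dat) == 0) abort(paste0("Empty trace file: ", path))
  if (ncol(dat) > 2) dat <- dat[, 1:2]
  for (j in seq_len(ncol(dat))) {
    col <- suppressWarnings(as.numeric(dat[[j]]))
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      abort(paste0("Non-numeric value in trace file at data row ", bad,
                   ", column ", j, "."))
    }
    dat[[j]] <- col
  }
  if (ncol(dat) == 1) {
    if (is.null(sampling_rate)) {
      abort(paste0("One-column trace files need an explicit `sampling_rate` ",
                   "(none found in ", path, ")."))
    }
    return(new_trace(dat[[1]], sampling_rate = sampling_rate))
  }
  tm <- dat[[1]]
  dts <- diff(tm)
  if (length(dts) > 0) {
    dt <- stats::median(dts)
    if (dt <= 0 || any(abs(dts - dt) > rtol * max(abs(dt), 1e-12) + 1e-12)) {
      abort("Timestamps in trace file are not uniformly sampled.")
    }
  } else {
    dt <- if (is.null(sampling_rate)) 4e-4 else 1 / sampling_rate
  }
  if (!is.null(sampling_rate) && abs(dt - 1 / sampling_rate) > rtol * dt) {
    warn(sprintf(
      "Timestamps imply %.6g Hz, overriding the requested %.6g Hz.",
      1 / dt, sampling_rate
    ))
  }
  out <- tibble::tibble(time = tm - tm[1], value = dat[[2]])
  attr(out, "units_label") <- "signal"
  out
}

#' Write a trace as TSV
#'
#' Two columns, `time` and `value`, full precision; `read_trace()` round-trips
#' the values exactly.
#'
#' @param trace Trace tibble or numeric vector.
#' @param path Output path.
#' @param sampling_rate Used when `trace` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sampling_rate = 2500) {
  if (!is.data.frame(trace)) trace <- new_trace(trace, sampling_rate)
  df <- tibble::tibble(time = trace$time, value = trace$value)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write detection results as a step table and a JSON run report
#'
#' The step table (TSV) has columns `step_index` (0-based sample index),
#' `time_s`, `size`, `se` and `t_p_value`; a baseline-only fit yields a
#' header-only table. The JSON report records the selected model, the BIC
#' elimination path, the AR noise model used for whitening, and the
#' configuration, and is byte-stable for identical inputs.
#'
#' @param fit A `step_fit` from [detect_steps()], [fit_gls()] or
#'   [backward_select()].
#' @param steps_path Path for the TSV step table.
#' @param report_path Path for the JSON report (optional; skipped if `NULL`).
#' @return A list with the paths written, invisibly.
#' @export
write_results <- function(fit, steps_path, report_path = NULL) {
  stopifnot(inherits(fit, "step_fit"))
  tab <- tidy(fit)
  readr::write_tsv(tab, steps_path)
  if (!is.null(report_path)) {
    report <- list(
      tool = "stepgls",
      version = as.character(utils::packageVersion("stepgls")),
      n_steps = length(fit$model$step_indices),
      model = list(
        baseline = fit$model$baseline,
        step_indices = fit$model$step_indices,
        step_sizes = fit$model$step_sizes,
        n = fit$model$n,
        dt = fit$model$dt
      ),
      fit = list(
        loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
        sigma2 = fit$sigma2
      ),
      ar_model = list(
        order = fit$noise$order,
        coefficients = fit$noise$coefficients,
        innovation_sd = fit$noise$innovation_sd
      ),
      bic_path = if (!is.null(fit$path)) {
        lapply(seq_len(nrow(fit$path)), function(i) as.list(fit$path[i, ]))
      },
      config = fit$config
    )
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(list(steps = steps_path, report = report_path))
}

#' Export a correlogram or eta profile as TSV
#'
#' @param x A tibble (e.g. from [correlogram()], [eta_profile()] or
#'   [build_superset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
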