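#' Compute relative fluorescence change (dF/F)
#'
#' Basal fluorescence \eqn{F_0} is the mean of the raw signal over the
#' `baseline_window` seconds preceding `stimulus_onset`; the trace becomes
#' \eqn{(F - F_0)/F_0}. The first `discard_first` seconds of illumination
#' (initial bleaching) are dropped before anything else.
#'
#' @param raw A tibble with columns `time_s`, `value` (raw fluorescence).
#' @param stimulus_onset Stimulus onset time in seconds.
#' @param baseline_window Length of the pre-onset baseline, seconds (default 4).
#' @param discard_first Leading crop in seconds (default 1).
#' @return A tibble `time_s`, `value` with `value` in dF/F units.
#' @export
compute_dff <- function(raw, stimulus_onset, baseline_window = 4,
                        discard_first = 1) {
  assert_columns(raw, c("time_s", "value"), "raw")
  if (discard_first > 0) {
    raw <- dplyr::filter(raw, .data$time_s >= min(.data$time_s) + discard_first)
  }
  t0 <- stimulus_onset - baseline_window
  if (t0 < min(raw$time_s) - 1e-9 || stimulus_onset > max(raw$time_s) + 1e-9) {
    stop("baseline window lies outside the record", call. = FALSE)
  }
  base <- raw$value[raw$time_s >= t0 & raw$time_s < stimulus_onset]
  if (length(base) < 2) {
    stop("baseline window must contain at least 2 samples", call. = FALSE)
  }
  f0 <- mean(base)
  if (f0 <= 0) stop("non-positive baseline fluorescence (F0 <= 0)", call. = FALSE)
  tibble::tibble(time_s = raw$time_s, value = (raw$value - f0) / f0)
}

#' Resample a trace onto a uniform grid by linear interpolation
#'
#' @param trace A tibble with `time_s` (strictly increasing) and `value`.
#' @param target_rate Target sampling rate in Hz.
#' @return A tibble on the uniform grid; no extrapolation beyond the original
#'   support.
#' @export
resample_uniform <- function(trace, target_rate) {
  assert_columns(trace, c("time_s", "value"), "trace")
  if (nrow(trace) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(trace$time_s) <= 0)) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  dt <- 1 / target_rate
  grid <- seq(
    ceiling(trace$time_s[1] / dt - 1e-9) * dt,
    floor(trace$time_s[nrow(trace)] / dt + 1e-9) * dt,
    by = dt
  )
  v <- stats::approx(trace$time_s, trace$value, xout = grid, rule = 1)$y
  tibble::tibble(time_s = grid, value = v)
}

#' Remove a linear bleaching trend (Syp-pHTomato signals)
#'
#' Fits and subtracts a linear trend. When several traces are supplied
#' (identified by `group_cols`), a single shared slope is estimated across
#' all of them (per odorant in practice: the bleaching slope is glomerulus-
#' and concentration-independent) with per-trace intercepts.
#'
#' @param traces Tibble with `time_s`, `value`, optionally `signal_kind` and
#'   identifier columns.
#' @param fit_window Length-2 numeric `c(from, to)` restricting the trend
#'   fit, or `NULL` for the whole trace.
#' @param group_cols Character vector of columns identifying individual
#'   traces (default: `trial_id` and friends, if present).
#' @param force Set `TRUE` to apply to non-pHTomato signals.
#' @return The input tibble with the trend removed from `value`; the shared
#'   slope is attached as attribute `bleach_slope`.
#' @export
remove_linear_bleach <- function(traces, fit_window = NULL, group_cols = NULL,
                                 force = FALSE) {
  assert_columns(traces, c("time_s", "value"), "traces")
  if (!force && "signal_kind" %in% names(traces) &&
    !all(traces$signal_kind == "phtomato")) {
    stop("bleach removal is meant for pHTomato signals (use force = TRUE to override)",
      call. = FALSE
    )
  }
  group_cols <- group_cols %||%
    intersect(c("trial_id", "glomerulus", "concentration", "animal_id"), names(traces))
  grp <- if (length(group_cols)) {
    interaction(traces[group_cols], drop = TRUE)
  } else {
    factor(rep(1L, nrow(traces)))
  }
  in_win <- if (is.null(fit_window)) {
    rep(TRUE, nrow(traces))
  } else {
    traces$time_s >= fit_window[1] & traces$time_s <= fit_window[2]
  }
  # shared slope: pooled within-trace least squares
  sxx <- 0
  sxy <- 0
  for (g in levels(grp)) {
    i <- grp == g & in_win
    tc <- traces$time_s[i] - mean(traces$time_s[i])
    sxx <- sxx + sum(tc^2)
    sxy <- sxy + sum(tc * traces$value[i])
  }
  slope <- sxy / sxx
  out <- traces
  for (g in levels(grp)) {
    i <- grp == g
    iw <- grp == g & in_win
    intercept <- mean(traces$value[iw]) - slope * mean(traces$time_s[iw])
    out$value[i] <- traces$value[i] - intercept - slope * traces$time_s[i]
  }
  attr(out, "bleach_slope") <- slope
  out
}

#' Average trials and compute the standard error of the mean
#'
#' @param traces Long tibble with `time_s`, `value` and a `trial_id` column;
#'   all trials must share the time grid.
#' @return A tibble `time_s`, `mean`, `sem`, `n_trials`. With a single trial
#'   `sem` is 0 by convention and the result carries
#'   `attr(, "sem_degenerate") = TRUE`.
#' @export
average_trials <- function(traces) {
  assert_columns(traces, c("time_s", "value", "trial_id"), "traces")
  counts <- dplyr::count(traces, .data$time_s)
  if (length(unique(counts$n)) != 1) {
    stop("trials do not share a common time grid", call. = FALSE)
  }
  n <- counts$n[1]
  out <- dplyr::summarise(dplyr::group_by(traces, .data$time_s),
    mean = mean(.data$value),
    sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
    n_trials = dplyr::n(), .groups = "drop"
  )
  if (n == 1) attr(out, "sem_degenerate") <- TRUE
  out
}

#' Normalise each trace to its response to the first odor pulse
#'
#' Divides each trace by its own peak response within the first valve-open
#' run (plus `latency`), so that after normalisation every first-pulse peak
#' equals 1.
#'
#' @param traces Long tibble with `time_s`, `value` and optionally `trial_id`.
#' @param valve A [valve_sequence()] on a compatible grid.
#' @param latency Peak-search extension past valve closure, seconds.
#' @return The normalised tibble.
#' @export
normalize_to_first_pulse <- function(traces, valve, latency = 0.3) {
  assert_columns(traces, c("time_s", "value"), "traces")
  runs <- valve_runs(valve)
  open <- runs[runs$state == 1, ]
  if (nrow(open) == 0) stop("valve has no open epoch", call. = FALSE)
  w0 <- open$onset_s[1]
  w1 <- open$offset_s[1] + latency
  grp <- if ("trial_id" %in% names(traces)) {
    traces$trial_id
  } else {
    rep(1L, nrow(traces))
  }
  out <- traces
  for (g in unique(grp)) {
    i <- grp == g
    peak <- max(traces$value[i & traces$time_s >= w0 & traces$time_s <= w1])
    if (!is.finite(peak) || peak <= 0) {
      stop("first-pulse peak must be positive", call. = FALSE)
    }
    out$value[i] <- traces$value[i] / peak
  }
  out
}

# Maximal runs of a valve sequence, with onset/offset times.
valve_runs <- function(valve) {
  assert_columns(valve, c("time_s", "state"), "valve")
  r <- rle(valve$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- grid_dt(valve$time_s)
  tibble::tibble(
    state = r$values,
    onset_s = valve$time_s[starts],
    offset_s = valve$time_s[ends] + dt,
    duration_s = r$lengths * dt
  )
}

#' Read and write the tidy trace-table CSV schema
#'
#' Columns: `time_s`, `value`, `signal_kind`, `sensor`, `cell_type`,
#' `glomerulus`, `odorant`, `log10_dilution`, `trial_id`, `animal_id` (UTF-8,
#' header required). Missing metadata columns are filled with `NA` on write.
#'
#' @param traces A tibble with at least `time_s` and `value`.
#' @param path File path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` the
#'   validated tibble.
#' @export
write_traces <- function(traces, path) {
  assert_columns(traces, c("time_s", "value"), "traces")
  schema <- c(
    "time_s", "value", "signal_kind", "sensor", "cell_type",
    "glomerulus", "odorant", "log10_dilution", "trial_id", "animal_id"
  )
  out <- traces
  for (col in setdiff(schema, names(out))) out[[col]] <- NA
  readr::write_csv(out[schema], path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trace_table(df)
  df
}

# Schema validation with row-number reporting.
validate_trace_table <- function(df, what = "trace table") {
  assert_columns(df, c("time_s", "value"), what)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad)) {
    stop(sprintf(
      "%s has non-finite time_s/value at row(s): %s", what,
      paste(utils::head(bad, 10), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
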