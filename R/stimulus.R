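#' Generate a pseudorandom binary valve sequence
#'
#' The odor delivery valve is re-drawn every `dt_update` seconds (open with
#' probability `open_probability`), and run lengths of either state are
#' constrained to `[min_run, max_run]`: a state is held until it has lasted
#' `min_run`, and a switch is forced once it has lasted `max_run` (run-level
#' rejection of out-of-bound runs). With the defaults this yields 2-minute
#' flicker sequences with 300 ms state updates and runs between 300 ms and
#' 2.7 s, sampled on a uniform 20 Hz grid.
#'
#' @param duration Total duration in seconds.
#' @param dt_update State-redraw interval in seconds (default 0.3).
#' @param min_run,max_run Bounds on the duration of any maximal run of either
#'   state, in seconds. `min_run` must be a multiple of `dt_update`.
#' @param open_probability Probability that a redraw lands on "open". See
#'   [calibrate_open_probability()] to target a realized stimulus CV.
#' @param seed Integer seed; identical `(seed, params)` give identical output.
#' @param sample_rate Output sampling rate in Hz (default 20, the imaging
#'   acquisition rate). `sample_rate * dt_update` must be an integer.
#'
#' @return A tibble of class `valve_sequence` with columns `time_s` and
#'   `state` (0/1), carrying the generation parameters as attributes.
#' @examples
#' v <- valve_sequence(duration = 12, seed = 1)
#' table(v$state)
#' @export
valve_sequence <- function(duration = 120, dt_update = 0.3, min_run = 0.3,
                           max_run = 2.7, open_probability = 0.5, seed = NULL,
                           sample_rate = 20) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (dt_update <= 0 || dt_update > max_run) {
    stop("dt_update must be in (0, max_run]", call. = FALSE)
  }
  if (min_run > max_run) stop("min_run must not exceed max_run", call. = FALSE)
  if (open_probability < 0 || open_probability > 1) {
    stop("open_probability must be in [0, 1]", call. = FALSE)
  }
  spb <- sample_rate * dt_update
  if (abs(spb - round(spb)) > 1e-8) {
    stop("sample_rate * dt_update must be an integer", call. = FALSE)
  }
  spb <- as.integer(round(spb))
  hold_bins <- as.integer(round(min_run / dt_update))
  if (abs(min_run / dt_update - hold_bins) > 1e-8 || hold_bins < 1) {
    stop("min_run must be a positive multiple of dt_update", call. = FALSE)
  }
  max_bins <- if (is.finite(max_run)) {
    as.integer(floor(max_run / dt_update + 1e-8))
  } else {
    .Machine$integer.max
  }
  n_bins <- as.integer(ceiling(duration / dt_update))
  n_samples <- as.integer(round(duration * sample_rate))

  states <- if (open_probability %in% c(0, 1)) {
    # degenerate probability: constant state (run bounds cannot apply)
    rep(as.integer(open_probability), n_bins)
  } else {
    with_seed_or_not(seed, {
    st <- integer(n_bins)
    run <- 0L
    cur <- NA_integer_
    for (i in seq_len(n_bins)) {
      if (is.na(cur)) {
        s <- as.integer(stats::runif(1) < open_probability)
      } else if (run < hold_bins) {
        s <- cur # minimum run not yet reached: hold
      } else if (run >= max_bins) {
        s <- 1L - cur # maximum run reached: forced switch
      } else {
        s <- as.integer(stats::runif(1) < open_probability)
      }
      run <- if (!is.na(cur) && s == cur) run + 1L else 1L
      cur <- s
      st[i] <- s
    }
    st
    })
  }

  state <- rep(states, each = spb)[seq_len(n_samples)]
  out <- tibble::tibble(
    time_s = (seq_len(n_samples) - 1L) / sample_rate,
    state = state
  )
  structure(out,
    class = c("valve_sequence", class(out)),
    dt_update = dt_update, min_run = min_run, max_run = max_run,
    open_probability = open_probability, seed = seed,
    sample_rate = sample_rate, duration = duration
  )
}

#' Calibrate the redraw probability to a target stimulus CV
#'
#' For a binary sequence with stationary open fraction \eqn{q}, the
#' coefficient of variation is \eqn{\sqrt{(1-q)/q}}. Under the run-truncated
#' redraw process the open fraction differs from the redraw probability
#' because long runs of either state are cut off at `max_run`; the truncated
#' geometric run-length distribution gives mean run lengths
#' \eqn{E = (1-p^m)/(1-p)} with \eqn{m} the maximum number of update bins,
#' from which the stationary open fraction follows. This function solves for
#' the redraw probability whose stationary open fraction matches the target
#' CV. It assumes `min_run == dt_update` (the default protocol).
#'
#' @param target_cv Desired coefficient of variation of the binary state.
#' @param dt_update,max_run As in [valve_sequence()].
#' @return The calibrated redraw probability (scalar).
#' @examples
#' calibrate_open_probability(0.9) # approx 0.55
#' @export
calibrate_open_probability <- function(target_cv, dt_update = 0.3,
                                       max_run = 2.7) {
  if (target_cv <= 0) stop("target_cv must be positive", call. = FALSE)
  q_star <- 1 / (1 + target_cv^2)
  m <- as.integer(floor(max_run / dt_update + 1e-8))
  open_frac <- function(p) {
    e_open <- (1 - p^m) / (1 - p)
    e_closed <- (1 - (1 - p)^m) / p
    e_open / (e_open + e_closed)
  }
  stats::uniroot(function(p) open_frac(p) - q_star,
    interval = c(1e-6, 1 - 1e-6), tol = 1e-10
  )$root
}

#' Scale a valve sequence by a nominal odor concentration
#'
#' The stimulus is the binary valve state multiplied by the nominal gas
#' volumetric dilution: \eqn{s(t) = C v(t)}.
#'
#' @param valve A [valve_sequence()].
#' @param concentration Nominal dilution \eqn{C \ge 0} (dimensionless).
#' @return A tibble of class `stimulus_trace` with columns `time_s`, `value`.
#' @export
scale_stimulus <- function(valve, concentration) {
  if (concentration < 0) stop("concentration must be non-negative", call. = FALSE)
  assert_columns(valve, c("time_s", "state"), "valve")
  out <- tibble::tibble(time_s = valve$time_s, value = concentration * valve$state)
  structure(out,
    class = c("stimulus_trace", class(out)),
    concentration = concentration,
    sample_rate = attr(valve, "sample_rate") %||% (1 / grid_dt(valve$time_s)),
    valve = valve
  )
}

#' Background-plus-pulse stimulus protocol
#'
#' Builds the piecewise-constant protocol used for background-adaptation
#' experiments: after a clean-air baseline, a test pulse is presented
#' isolated, then (after a gap) a constant odor background is delivered with
#' the same test pulse superimposed part-way through.
#'
#' @param background_conc,pulse_conc Nominal dilutions (\eqn{\ge 0}).
#' @param background_duration Background epoch length in seconds (default 15).
#' @param pulse_onset Pulse onset within the background epoch, seconds from
#'   background start.
#' @param pulse_duration Test-pulse duration in seconds.
#' @param sample_rate Hz.
#' @param baseline Leading clean-air epoch, seconds.
#' @param gap Clean-air gap between the isolated pulse and the background
#'   epoch, seconds.
#' @return A `stimulus_trace` tibble; total duration is the sum of the
#'   declared epochs.
#' @export
background_pulse_protocol <- function(background_conc, pulse_conc,
                                      background_duration = 15,
                                      pulse_onset = 7.5, pulse_duration = 1,
                                      sample_rate = 20, baseline = 5, gap = 10) {
  if (background_conc < 0 || pulse_conc < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (pulse_onset < 0 || pulse_onset + pulse_duration > background_duration) {
    stop("pulse extends beyond the background epoch", call. = FALSE)
  }
  total <- baseline + pulse_duration + gap + background_duration
  n <- as.integer(round(total * sample_rate))
  time_s <- (seq_len(n) - 1L) / sample_rate
  value <- numeric(n)
  # isolated pulse
  iso_on <- baseline
  value[time_s >= iso_on & time_s < iso_on + pulse_duration] <- pulse_conc
  # background epoch with superimposed pulse
  bg_on <- baseline + pulse_duration + gap
  in_bg <- time_s >= bg_on & time_s < bg_on + background_duration
  value[in_bg] <- background_conc
  on_bg <- time_s >= bg_on + pulse_onset &
    time_s < bg_on + pulse_onset + pulse_duration
  value[on_bg] <- pulse_conc
  out <- tibble::tibble(time_s = time_s, value = value)
  structure(out,
    class = c("stimulus_trace", class(out)),
    concentration = pulse_conc, sample_rate = sample_rate,
    epochs = c(
      baseline = baseline, isolated_pulse = pulse_duration, gap = gap,
      background = background_duration
    )
  )
}

#' Write or read a stimulus/valve table as tidy CSV
#'
#' Columns: `time_s`, `value`, `channel`, `seed`, `params_hash`. Round-trips
#' losslessly through [read_stimulus_csv()].
#'
#' @param x A `valve_sequence` or `stimulus_trace`.
#' @param path File path.
#' @param channel Label stored in the `channel` column.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns a tibble with the stored columns.
#' @export
write_stimulus_csv <- function(x, path, channel = "stimulus") {
  value <- if ("value" %in% names(x)) x$value else x$state
  params <- attributes(x)[c(
    "dt_update", "min_run", "max_run", "open_probability",
    "sample_rate", "duration", "concentration"
  )]
  out <- tibble::tibble(
    time_s = x$time_s, value = value, channel = channel,
    seed = (attr(x, "seed") %||% NA_integer_),
    params_hash = rlang::hash(params)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
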