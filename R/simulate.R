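#' Ground-truth parameter set for the synthetic-data generator
#'
#' Collects the generative parameters of one glomerulus/cell type: a front-end
#' Hill dose-response nonlinearity applied to the raw stimulus, a parametric
#' temporal filter ([filter_spec()]), an optional output static nonlinearity,
#' slow multiplicative adaptation (degree `d` and timescale `tau_slow`),
#' sensor kinetics, and the noise model (additive Gaussian noise plus a
#' lognormal per-trial gain).
#'
#' @param filter A [filter_spec()].
#' @param front_end `NULL` (identity) or a list with `f_max`, `H`, `n`,
#'   `baseline` describing a Hill function of concentration.
#' @param static_nl `NULL` (identity) or a list `list(a =, b =)` for a linear
#'   output function.
#' @param d Degree of slow adaptation in `[0, 1]` (0 = none, 1 = complete).
#' @param tau_slow Timescale of slow adaptation, seconds, in `(0, 40]`.
#' @param sensor A [sensor_model()] or `NULL` for no sensor filtering.
#' @param noise_sd Additive noise sd in response units, or `NULL` to use
#'   `noise_frac`.
#' @param noise_frac If `noise_sd` is `NULL`, noise sd as a fraction of the
#'   max clean response of the simulated condition (default 0.1).
#' @param trial_gain_sd Lognormal sd of the per-trial multiplicative gain.
#' @param n_trials Number of trials to simulate.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(filter, front_end = NULL, static_nl = NULL, d = 0,
                         tau_slow = 8, sensor = sensor_model("GCaMP3"),
                         noise_sd = NULL, noise_frac = 0.1,
                         trial_gain_sd = 0.1, n_trials = 7, seed = NULL) {
  stopifnot(inherits(filter, "filter_spec"))
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  if (tau_slow <= 0 || tau_slow > 40) {
    stop("tau_slow must be in (0, 40] seconds", call. = FALSE)
  }
  if (!is.null(noise_sd) && noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(
      filter = filter, front_end = front_end, static_nl = static_nl,
      d = d, tau_slow = tau_slow, sensor = sensor, noise_sd = noise_sd,
      noise_frac = noise_frac, trial_gain_sd = trial_gain_sd,
      n_trials = n_trials, seed = seed
    ),
    class = "ground_truth"
  )
}

#' @describeIn ground_truth ORN-like preset: monophasic unit-area exponential
#'   filter, Hill front end with midpoint `H` and exponent `n_hill`, no slow
#'   adaptation.
#' @param tau_filter Filter timescale in seconds.
#' @param H,n_hill Hill midpoint (dilution units) and exponent of the
#'   front-end dose-response.
#' @param ... Passed on to `ground_truth()`.
#' @export
orn_truth <- function(tau_filter = 0.5, H = 1e-4, n_hill = 1.5, ...) {
  ground_truth(
    filter = filter_spec("k1", A1 = 1 / tau_filter, tau1 = tau_filter),
    front_end = list(f_max = 1, H = H, n = n_hill, baseline = 0),
    d = 0, ...
  )
}

#' @describeIn ground_truth PN-like preset: biphasic filter and slow
#'   multiplicative adaptation with degree `d`.
#' @export
pn_truth <- function(d = 0.6, tau_slow = 8, H = 1e-4, n_hill = 1.5, ...) {
  ground_truth(
    filter = filter_spec("k3", A1 = 4, tau1 = 0.3, A2 = -0.5, tau2 = 1.2),
    front_end = list(f_max = 1, H = H, n = n_hill, baseline = 0),
    d = d, tau_slow = tau_slow, ...
  )
}

#' @describeIn ground_truth Syp-pHTomato-like preset: double-exponential
#'   filter with a fast positive and a slow negative lobe, no sensor stage.
#' @export
phtomato_truth <- function(...) {
  ground_truth(
    filter = filter_spec("k3", A1 = 1, tau1 = 0.35, A2 = -0.02, tau2 = 10),
    sensor = NULL, ...
  )
}

hill_value <- function(x, f_max, H, n, baseline = 0) {
  baseline + f_max * x^n / (x^n + H^n)
}

apply_front_end <- function(value, front_end) {
  if (is.null(front_end)) {
    return(value)
  }
  hill_value(
    value, front_end$f_max, front_end$H, front_end$n,
    front_end$baseline %||% 0
  )
}

apply_static_nl <- function(value, static_nl) {
  if (is.null(static_nl)) {
    return(value)
  }
  static_nl$a * value + (static_nl$b %||% 0)
}

# Deterministic part of the generative cascade:
# front-end -> temporal filter -> output nonlinearity -> sensor kinetics
# -> slow multiplicative gain (1-d) + d exp(-t/tau_slow).
sim_clean <- function(stimulus, truth) {
  dt <- grid_dt(stimulus$time_s)
  support <- max(4, if (truth$filter$family == "k3") 4 * truth$filter$tau2 else 0)
  # midpoint sampling of the kernel keeps the discrete convolution's DC gain
  # equal to the continuous filter area to O(dt^2)
  lags <- seq(0, support, by = dt) + dt / 2
  k <- eval_filter(truth$filter, lags)
  g <- apply_front_end(stimulus$value, truth$front_end)
  lin <- causal_conv(g, k, dt)
  clean <- apply_static_nl(lin, truth$static_nl)
  if (!is.null(truth$sensor)) clean <- exp_conv(clean, truth$sensor$tau, dt)
  if (truth$d > 0) {
    g_slow <- (1 - truth$d) + truth$d * exp(-stimulus$time_s / truth$tau_slow)
    clean <- clean * g_slow
  }
  clean
}

sim_trials <- function(stimulus, truth, clean, extra = NULL, cell_type = NA) {
  noise_sd <- truth$noise_sd %||% ((truth$noise_frac %||% 0) * max(abs(clean)))
  n <- length(clean)
  trials <- with_seed_or_not(truth$seed, {
    purrr::map(seq_len(truth$n_trials), function(i) {
      gain <- if (truth$trial_gain_sd > 0) {
        stats::rlnorm(1, -truth$trial_gain_sd^2 / 2, truth$trial_gain_sd)
      } else {
        1
      }
      gain * clean + (extra %||% 0) + stats::rnorm(n, 0, noise_sd)
    })
  })
  out <- tibble::tibble(
    time_s = rep(stimulus$time_s, truth$n_trials),
    value = unlist(trials),
    trial_id = rep(seq_len(truth$n_trials), each = n),
    cell_type = cell_type
  )
  structure(out,
    class = c("synthetic_traces", class(out)),
    truth = truth, stimulus = stimulus, clean = clean, noise_sd = noise_sd
  )
}

#' Simulate glomerular responses from the generative encoding model
#'
#' `simulate_orn()` produces ORN-like calcium responses: the stimulus passes
#' through the front-end Hill nonlinearity, a monophasic temporal filter, the
#' output nonlinearity and the sensor kinetics; trials differ by a lognormal
#' gain and additive Gaussian noise. `simulate_pn()` allows biphasic filters
#' and multiplies the output by the slow-depression gain trajectory
#' \eqn{g(t) = (1-d) + d e^{-t/\tau_{slow}}} from stimulus onset.
#' `simulate_syp_phtomato()` generates vesicle-release-reporter signals from a
#' double-exponential filter (fast positive, slow negative lobe) with an
#' additive linear bleaching drift.
#'
#' @param stimulus A `stimulus_trace` (see [scale_stimulus()]).
#' @param truth A [ground_truth()].
#' @return A tibble of class `synthetic_traces` with columns `time_s`,
#'   `value`, `trial_id`, `cell_type`, carrying `truth`, `stimulus` and the
#'   noiseless `clean` trace as attributes.
#' @examples
#' v <- valve_sequence(duration = 20, seed = 1)
#' s <- scale_stimulus(v, 1e-4)
#' tr <- simulate_orn(s, orn_truth(seed = 1))
#' @export
simulate_orn <- function(stimulus, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is_monophasic(truth$filter)) {
    stop("ORN preset requires a monophasic (k1/k2) filter", call. = FALSE)
  }
  if (truth$d != 0) stop("ORN preset requires d = 0", call. = FALSE)
  clean <- sim_clean(stimulus, truth)
  sim_trials(stimulus, truth, clean, cell_type = "ORN")
}

#' @rdname simulate_orn
#' @export
simulate_pn <- function(stimulus, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$d < 0 || truth$d > 1) stop("d must be in [0, 1]", call. = FALSE)
  clean <- sim_clean(stimulus, truth)
  sim_trials(stimulus, truth, clean, cell_type = "PN")
}

#' @rdname simulate_orn
#' @param bleach_slope Linear drift added to the signal, response units per
#'   second.
#' @export
simulate_syp_phtomato <- function(stimulus, truth, bleach_slope = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  f <- truth$filter
  if (f$family != "k3" || f$A1 <= 0 || f$A2 >= 0 || f$tau2 <= f$tau1) {
    stop("Syp-pHTomato preset requires a k3 filter with A1 > 0, A2 < 0, tau2 > tau1",
      call. = FALSE
    )
  }
  clean <- sim_clean(stimulus, truth)
  out <- sim_trials(stimulus, truth, clean,
    extra = bleach_slope * stimulus$time_s, cell_type = "ORN"
  )
  out$signal_kind <- "phtomato"
  out
}

#' Simulate an adapting firing-rate response
#'
#' Phasic-tonic rate model: the output is the stimulus minus an adaptive
#' state that tracks a fraction `adaptation_fraction` of the stimulus with
#' timescale `tau_fr`, clipped at zero. A step input produces a peak that
#' decays to `1 - adaptation_fraction` of its initial value.
#'
#' @param stimulus A `stimulus_trace`.
#' @param adaptation_fraction Fraction of the steady response removed by
#'   adaptation, in `[0, 1]`.
#' @param tau_fr Adaptation timescale in seconds (order 0.1 s for ORN firing).
#' @param rate_scale Output scale (spikes/s per stimulus unit).
#' @return A tibble with columns `time_s`, `value` (`signal_kind` = firing rate).
#' @export
simulate_firing_rate <- function(stimulus, adaptation_fraction = 0.7,
                                 tau_fr = 0.1, rate_scale = 1) {
  if (tau_fr <= 0) stop("tau_fr must be positive", call. = FALSE)
  dt <- grid_dt(stimulus$time_s)
  drive <- adaptation_fraction * stimulus$value
  adapt <- exp_conv(c(0, drive), tau_fr, dt)[-1] # unadapted before onset
  rate <- pmax(0, rate_scale * (stimulus$value - adapt))
  tibble::tibble(time_s = stimulus$time_s, value = rate, signal_kind = "firing_rate")
}

#' Default glomerulus parameter sets for population simulations
#'
#' Five glomeruli with Hill midpoints staggered across the tested
#' concentration range (receptor recruitment), filter timescales spread over
#' 0.3-1 s, shared sensor kinetics, and a common degree of slow adaptation
#' for the PN variant.
#'
#' @param n_glomeruli Number of glomeruli.
#' @param H_range Log10 range of Hill midpoints (dilution units).
#' @param tau_range Range of filter timescales, seconds.
#' @param d,tau_slow Slow-adaptation parameters used by the PN variant.
#' @param seed Base seed; each glomerulus/concentration combination derives
#'   its own sub-seed.
#' @param ... Passed to [ground_truth()] (noise model, trial counts, ...).
#' @return A list of `ground_truth` objects, one per glomerulus.
#' @export
population_specs <- function(n_glomeruli = 5, H_range = c(-5, -3),
                             tau_range = c(0.3, 1), d = 0.57, tau_slow = 8,
                             seed = NULL, ...) {
  H <- 10^seq(H_range[1], H_range[2], length.out = n_glomeruli)
  tau <- seq(tau_range[1], tau_range[2], length.out = n_glomeruli)
  purrr::map(seq_len(n_glomeruli), function(g) {
    ground_truth(
      filter = filter_spec("k1", A1 = 1 / tau[g], tau1 = tau[g]),
      front_end = list(f_max = 1, H = H[g], n = 1.5, baseline = 0),
      d = d, tau_slow = tau_slow, seed = seed, ...
    )
  })
}

#' Simulate a multi-glomerulus population response
#'
#' Each glomerulus responds to the same valve sequence scaled to each tested
#' concentration through its own front end and filter. The ORN variant forces
#' the degree of slow adaptation to zero; the PN variant keeps each
#' glomerulus's `d` (front ends are shared between variants). Trials are
#' averaged, mirroring the analysis of mean responses.
#'
#' @param stimuli A list of `stimulus_trace` objects, one per concentration,
#'   sharing the same time grid.
#' @param glomerulus_specs A list of [ground_truth()] objects (length >= 2),
#'   e.g. from [population_specs()].
#' @param cell_type `"ORN"` or `"PN"`.
#' @return A tibble of class `synthetic_population` with columns
#'   `concentration`, `glomerulus`, `time_s`, `value` (trial-averaged) and
#'   `n_trials`; the noiseless traces are in `attr(, "clean")`.
#' @export
simulate_population <- function(stimuli, glomerulus_specs,
                                cell_type = c("ORN", "PN")) {
  cell_type <- match.arg(cell_type)
  if (length(glomerulus_specs) < 2) {
    stop("need at least 2 glomeruli", call. = FALSE)
  }
  grids <- purrr::map(stimuli, "time_s")
  if (length(unique(purrr::map_dbl(grids, length))) > 1 ||
    any(purrr::map_lgl(grids[-1], function(g) max(abs(g - grids[[1]])) > 1e-9))) {
    stop("stimuli must share a common time grid", call. = FALSE)
  }
  rows <- purrr::imap(stimuli, function(stim, ci) {
    purrr::imap(glomerulus_specs, function(spec, gi) {
      truth <- spec
      if (cell_type == "ORN") truth$d <- 0
      if (!is.null(spec$seed)) {
        truth$seed <- as.integer(spec$seed + 97L * gi + 1009L * as.integer(ci))
      }
      sim <- if (cell_type == "ORN") {
        simulate_orn(stim, truth)
      } else {
        simulate_pn(stim, truth)
      }
      avg <- dplyr::summarise(dplyr::group_by(sim, .data$time_s),
        value = mean(.data$value), .groups = "drop"
      )
      tibble::tibble(
        concentration = attr(stim, "concentration"),
        glomerulus = paste0("g", gi),
        time_s = avg$time_s, value = avg$value,
        clean = attr(sim, "clean"),
        n_trials = truth$n_trials
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  clean <- out$clean
  out$clean <- NULL
  structure(out,
    class = c("synthetic_population", class(out)),
    clean = clean, specs = glomerulus_specs, cell_type = cell_type
  )
}
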