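test_that("generators are deterministic and trials differ only by gain when noiseless", {
  s <- quick_stim(duration = 20, seed = 1)
  tru <- orn_truth(seed = 5, noise_frac = 0, trial_gain_sd = 0.2, n_trials = 3)
  sim1 <- simulate_orn(s, tru)
  sim2 <- simulate_orn(s, tru)
  expect_identical(sim1$value, sim2$value)

  wide <- tidyr::pivot_wider(sim1,
    names_from = "trial_id", values_from = "value",
    id_cols = "time_s"
  )
  r12 <- wide$`1` / wide$`2`
  keep <- abs(wide$`2`) > 1e-8
  expect_lt(stats::sd(r12[keep]), 1e-8) # constant ratio = pure gain
})

test_that("a unit-gain linear cascade reproduces the stimulus level at steady state", {
  # constant-open stimulus through identity front end, unit-area filter, no sensor
  v <- valve_sequence(duration = 20, open_probability = 1, max_run = Inf, seed = 1)
  s <- scale_stimulus(v, 0.37)
  sim <- simulate_orn(s, linear_truth(tau = 0.5, seed = 1))
  late <- sim$value[sim$time_s > 10]
  expect_equal(mean(late), 0.37, tolerance = 0.01)

  with_sensor <- simulate_orn(s, ground_truth(
    filter = filter_spec("k1", A1 = 2, tau1 = 0.5), front_end = NULL,
    sensor = sensor_model("GCaMP3"), noise_frac = 0, trial_gain_sd = 0,
    n_trials = 1, seed = 1
  ))
  expect_equal(
    mean(with_sensor$value[with_sensor$time_s > 10]), 0.37,
    tolerance = 0.01
  )
})

test_that("the generating Hill dose-response is recovered from peak responses", {
  v <- quick_valve(duration = 60, seed = 3)
  concs <- 10^seq(-5, -3, length.out = 6)
  tru <- function(seed) orn_truth(H = 1e-4, n_hill = 2, seed = seed, noise_frac = 0.02)
  dr <- purrr::map_dfr(seq_along(concs), function(i) {
    s <- scale_stimulus(v, concs[i])
    sim <- simulate_orn(s, tru(seed = 10 + i))
    pk <- extract_pulse_peaks(mean_trace(sim), v, smooth_s = 0.15)
    tibble::tibble(concentration = concs[i], peak_response = mean(pk$peak))
  })
  fe <- fit_front_end_nl(dr)
  expect_equal(unname(log10(fe$coef["H"])), -4, tolerance = 0.15)
  expect_equal(unname(fe$coef["n"]), 2, tolerance = 0.4)
})

test_that("PN slow depression scales the output multiplicatively", {
  s <- quick_stim(duration = 60, seed = 2)
  base <- pn_truth(d = 0, seed = 3, noise_frac = 0, trial_gain_sd = 0, n_trials = 1)
  full <- pn_truth(d = 0.6, tau_slow = 8, seed = 3, noise_frac = 0, trial_gain_sd = 0, n_trials = 1)
  r0 <- simulate_pn(s, base)
  r1 <- simulate_pn(s, full)
  g <- (1 - 0.6) + 0.6 * exp(-s$time_s / 8)
  expect_equal(r1$value, r0$value * g, tolerance = 1e-12)

  # complete adaptation: late response goes to zero
  r_complete <- simulate_pn(s, pn_truth(
    d = 1, tau_slow = 2, seed = 3,
    noise_frac = 0, trial_gain_sd = 0, n_trials = 1
  ))
  expect_lt(max(abs(r_complete$value[s$time_s > 30])), 1e-4 * max(abs(r_complete$value)))
  expect_error(pn_truth(d = 1.2), "d must be")
})

test_that("the injected decay timescale is recovered from noiseless PN peaks", {
  # periodic pulse train (0.9 s on/off) so each pulse has identical drive and
  # the peak envelope is exactly the slow-gain trajectory; the first 5 s are
  # dropped to let the filter/sensor cascade settle
  dt <- 0.05
  state <- rep(rep(c(1L, 0L), each = 18), length.out = 120 * 20)
  v <- tibble::tibble(time_s = (seq_along(state) - 1) * dt, state = state)
  s <- structure(
    tibble::tibble(time_s = v$time_s, value = 1e-4 * state),
    class = c("stimulus_trace", "tbl_df", "tbl", "data.frame"),
    concentration = 1e-4
  )
  sim <- simulate_pn(s, pn_truth(
    d = 0.6, tau_slow = 8, seed = 9,
    noise_frac = 0, trial_gain_sd = 0, n_trials = 1
  ))
  pk <- extract_pulse_peaks(mean_trace(sim), v)
  fit <- fit_peak_decay(pk[pk$onset_s >= 5, ], "exponential", n_boot = 0)
  expect_equal(fit$params[["tau"]], 8, tolerance = 0.05 * 8)
  # extrapolated adapted/initial ratio equals the injected 1 - d
  expect_equal(fit$r_inf / fit$r0, 0.4, tolerance = 0.05)
})

test_that("Syp-pHTomato traces carry a slow negative lobe and linear bleach", {
  v <- quick_valve(duration = 40, seed = 4)
  s0 <- scale_stimulus(valve_sequence(duration = 40, open_probability = 0, seed = 1), 1)
  tru <- phtomato_truth(seed = 2, noise_frac = 0, trial_gain_sd = 0, n_trials = 1)

  # zero stimulus: pure linear ramp at the bleach slope
  ramp <- simulate_syp_phtomato(s0, tru, bleach_slope = -0.01)
  expect_equal(ramp$value, -0.01 * s0$time_s, tolerance = 1e-12)

  # noiseless, bleach-free data: recovered filter is biphasic with tau2 > tau1
  s <- scale_stimulus(v, 1)
  sim <- simulate_syp_phtomato(s, tru, bleach_slope = 0)
  filt <- estimate_filter(s, mean_trace(sim), n_lags = 200, ridge_lambda = 1e-8)
  expect_lt(min(filt$coef), 0) # negative lobe present
  fit <- fit_parametric(filt, "k3", tau_starts = c(0.3, 1, 3, 10))
  expect_gt(fit$params[["tau2"]], fit$params[["tau1"]])
  expect_lt(fit$params[["A2"]], 0)

  expect_error(
    simulate_syp_phtomato(s, orn_truth(seed = 1)),
    "k3"
  )
})

test_that("the firing-rate model is phasic-tonic with the declared adaptation", {
  v <- valve_sequence(duration = 20, open_probability = 1, max_run = Inf, seed = 1)
  s <- scale_stimulus(v, 1)

  none <- simulate_firing_rate(s, adaptation_fraction = 0, tau_fr = 0.1)
  expect_equal(none$value, s$value, tolerance = 1e-9)

  step <- simulate_firing_rate(s, adaptation_fraction = 0.7, tau_fr = 0.5)
  peak <- max(step$value)
  late <- mean(step$value[s$time_s > 10])
  expect_equal(late / peak, 1 - 0.7, tolerance = 0.05)
  expect_true(all(step$value >= 0))
})

test_that("sensor-filtered firing rates under-predict the pulse-on-background response", {
  # the background adapts the rate; convolving the adapting rate with sensor
  # kinetics predicts a smaller pulse response on background than isolated
  prot <- background_pulse_protocol(
    background_conc = 0.5, pulse_conc = 1,
    background_duration = 15, pulse_onset = 10, pulse_duration = 1,
    baseline = 5, gap = 10
  )
  rate <- simulate_firing_rate(prot, adaptation_fraction = 0.7, tau_fr = 0.5)
  pred <- convolve_with_sensor(rate, sensor_model("GCaMP3"))
  t <- prot$time_s
  iso_peak <- max(pred$value[t >= 5 & t < 7])
  bg_start <- 5 + 1 + 10
  on_bg_peak <- max(pred$value[t >= bg_start + 10 & t < bg_start + 12]) -
    pred$value[which.min(abs(t - (bg_start + 10)))]
  expect_lt(on_bg_peak, iso_peak)
})

test_that("population simulations share stimuli and express recruitment", {
  v <- quick_valve(duration = 30, seed = 7)
  concs <- 10^c(-5, -4.3, -3.7, -3)
  stimuli <- lapply(concs, function(C) scale_stimulus(v, C))
  specs <- population_specs(seed = 7, noise_frac = 0)
  pop <- simulate_population(stimuli, specs, "ORN")
  expect_setequal(unique(pop$glomerulus), paste0("g", 1:5))

  # glomeruli above half their saturated response: non-decreasing with conc
  sat <- dplyr::summarise(
    dplyr::group_by(pop, .data$glomerulus),
    top = max(.data$value), .groups = "drop"
  )
  n_active <- vapply(concs, function(C) {
    m <- dplyr::summarise(
      dplyr::group_by(pop[pop$concentration == C, ], .data$glomerulus),
      peak = max(.data$value), .groups = "drop"
    )
    sum(m$peak > 0.5 * sat$top[match(m$glomerulus, sat$glomerulus)])
  }, numeric(1))
  expect_true(all(diff(n_active) >= 0))

  expect_error(simulate_population(stimuli, specs[1], "ORN"), "at least 2")
})

test_that("the noiseless linear stage obeys superposition", {
  v1 <- quick_valve(duration = 20, seed = 11)
  v2 <- quick_valve(duration = 20, seed = 12)
  s1 <- scale_stimulus(v1, 1)
  s2 <- scale_stimulus(v2, 1)
  s12 <- s1
  s12$value <- s1$value + s2$value
  tru <- linear_truth(tau = 0.4, seed = 1)
  r1 <- simulate_orn(s1, tru)$value
  r2 <- simulate_orn(s2, tru)$value
  r12 <- simulate_orn(s12, tru)$value
  expect_equal(r12, r1 + r2, tolerance = 1e-10)
})
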