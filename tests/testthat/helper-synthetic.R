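# Shared builders for synthetic fixtures (generated at test time).

quick_valve <- function(duration = 30, seed = 1, p = 0.5) {
  valve_sequence(duration = duration, open_probability = p, seed = seed)
}

quick_stim <- function(duration = 30, seed = 1, conc = 1e-4, p = 0.5) {
  scale_stimulus(quick_valve(duration, seed, p), conc)
}

# Linear-path truth: no front end, no output nonlinearity, no sensor.
linear_truth <- function(tau = 0.5, noise_frac = 0, n_trials = 1, seed = 1, ...) {
  ground_truth(
    filter = filter_spec("k1", A1 = 1 / tau, tau1 = tau),
    front_end = NULL, sensor = NULL, noise_frac = noise_frac,
    trial_gain_sd = 0, n_trials = n_trials, seed = seed, ...
  )
}

mean_trace <- function(sim) {
  avg <- average_trials(sim)
  tibble::tibble(time_s = avg$time_s, value = avg$mean)
}
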