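#' Default run configuration
#'
#' A nested list mirroring the analysis stages: stimulus construction,
#' generator ground truth, encoding-model estimation, adaptation analysis and
#' population analysis. Every artifact written by the `run_*()` functions
#' embeds the hash of the configuration and the seed, so identical configs
#' reproduce identical outputs.
#'
#' @param seed Integer seed routed to every stochastic stage.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(
    list(
      seed = as.integer(seed),
      stimulus = list(
        duration = 120, dt_update = 0.3, min_run = 0.3, max_run = 2.7,
        open_probability = 0.5, sample_rate = 20, concentration = 1e-4
      ),
      truth = list(
        cell_type = "ORN", tau_filter = 0.5, H = 1e-4, n_hill = 1.5,
        d = 0, tau_slow = 8, noise_frac = 0.1, trial_gain_sd = 0.1,
        n_trials = 7, sensor = "GCaMP3"
      ),
      estimator = list(
        n_lags = 80, ridge_lambda = NULL, nonlinearity = "auto",
        discard_s = 35, train_fraction = 2 / 3
      ),
      adaptation = list(latency = 0.3, n_bins = 10, sort_window = 12, tau_cap = 40),
      population = list(
        n_glomeruli = 5, mode = "timepoints", tau_integration = 0.54,
        concentrations = 10^c(-5, -4.3, -3.7, -3), center = FALSE, d = 0.57
      )
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1)
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[section]])) {
      for (key in names(user[[section]])) {
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

config_hash <- function(config) rlang::hash(unclass(config))

validate_config <- function(config) {
  st <- config$stimulus
  if (st$duration <= 0) stop("config: duration must be positive", call. = FALSE)
  if (config$truth$n_trials < 1) {
    stop("config: n_trials must be at least 1", call. = FALSE)
  }
  if (!config$truth$cell_type %in% c("ORN", "PN")) {
    stop("config: cell_type must be ORN or PN", call. = FALSE)
  }
  invisible(config)
}

config_truth <- function(config) {
  tr <- config$truth
  if (tr$cell_type == "ORN") {
    orn_truth(
      tau_filter = tr$tau_filter, H = tr$H, n_hill = tr$n_hill,
      noise_frac = tr$noise_frac, trial_gain_sd = tr$trial_gain_sd,
      n_trials = tr$n_trials, seed = config$seed,
      sensor = sensor_model(tr$sensor)
    )
  } else {
    pn_truth(
      d = tr$d, tau_slow = tr$tau_slow, H = tr$H, n_hill = tr$n_hill,
      noise_frac = tr$noise_frac, trial_gain_sd = tr$trial_gain_sd,
      n_trials = tr$n_trials, seed = config$seed,
      sensor = sensor_model(tr$sensor)
    )
  }
}

config_stimulus <- function(config) {
  st <- config$stimulus
  v <- valve_sequence(
    duration = st$duration, dt_update = st$dt_update, min_run = st$min_run,
    max_run = st$max_run, open_probability = st$open_probability,
    seed = config$seed, sample_rate = st$sample_rate
  )
  list(valve = v, stimulus = scale_stimulus(v, st$concentration))
}

#' Simulate a dataset and write its artifacts
#'
#' Writes `stimulus.csv` (tidy stimulus trace), `traces.csv` (trace-table
#' schema) and `truth.json` (the generative parameters plus seed and config
#' hash) into `out_dir`. Validation happens before any file is written.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config_stimulus(config)
  truth <- config_truth(config)
  traces <- if (config$truth$cell_type == "ORN") {
    simulate_orn(sim$stimulus, truth)
  } else {
    simulate_pn(sim$stimulus, truth)
  }
  traces$signal_kind <- "dff"
  traces$sensor <- config$truth$sensor
  traces$log10_dilution <- log10(config$stimulus$concentration)

  paths <- c(
    stimulus = file.path(out_dir, "stimulus.csv"),
    traces = file.path(out_dir, "traces.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_stimulus_csv(sim$stimulus, paths["stimulus"])
  write_traces(traces, paths["traces"])
  truth_out <- unclass(truth)
  truth_out$filter <- unclass(truth_out$filter)
  truth_out$sensor <- if (!is.null(truth$sensor)) unclass(truth$sensor)
  jsonlite::write_json(
    list(
      truth = truth_out, seed = config$seed,
      config_hash = config_hash(config)
    ),
    paths["truth"],
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}

#' Fit encoding models to a trace file and write model artifacts
#'
#' Reads the trace and stimulus CSVs (validating the schema with row-numbered
#' errors), averages trials, fits an LN model — and, unless `front_end =
#' FALSE`, an NLN model whose front end is estimated from the per-pulse
#' dose-response — selects the parametric filter family by BIC, and writes
#' `model_ln.json` (+ `model_nln.json`), `filter_fit.json` and a one-row
#' `summary.csv`.
#'
#' @param config A `run_config`.
#' @param trace_file,stimulus_file Input CSVs (see [write_traces()],
#'   [write_stimulus_csv()]).
#' @param out_dir Output directory.
#' @param front_end `NULL` for an LN model only; otherwise a
#'   `static_nonlinearity` from [fit_front_end_nl()], or a dose-response
#'   tibble (`concentration`, `peak_response`) to fit one from, enabling the
#'   NLN variant.
#' @return Named vector of output paths, invisibly.
#' @export
run_fit <- function(config, trace_file, stimulus_file, out_dir = ".",
                    front_end = NULL) {
  if (!file.exists(trace_file)) {
    stop(sprintf("trace file not found: %s", trace_file), call. = FALSE)
  }
  if (!file.exists(stimulus_file)) {
    stop(sprintf("stimulus file not found: %s", stimulus_file), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- read_traces(trace_file)
  stim_df <- read_stimulus_csv(stimulus_file)
  validate_trace_table(stim_df, "stimulus table")
  stimulus <- tibble::tibble(time_s = stim_df$time_s, value = stim_df$value)
  est <- config$estimator

  ln <- fit_ln(stimulus, traces,
    n_lags = est$n_lags, ridge_lambda = est$ridge_lambda,
    nonlinearity = est$nonlinearity, discard_s = est$discard_s,
    train_fraction = est$train_fraction
  )
  ffit <- select_filter_model(ln$filter)

  paths <- c(
    model_ln = file.path(out_dir, "model_ln.json"),
    filter_fit = file.path(out_dir, "filter_fit.json"),
    summary = file.path(out_dir, "summary.csv")
  )
  write_ln_model(ln, paths["model_ln"])
  write_filter_fit(ffit, paths["filter_fit"])

  summary_row <- dplyr::bind_cols(glance(ln), glance(ffit))
  if (!is.null(front_end)) {
    fe <- if (inherits(front_end, "static_nonlinearity")) {
      front_end
    } else {
      fit_front_end_nl(front_end)
    }
    nln <- fit_ln(stimulus, traces,
      n_lags = est$n_lags, ridge_lambda = est$ridge_lambda,
      nonlinearity = est$nonlinearity, front_end = fe,
      discard_s = est$discard_s, train_fraction = est$train_fraction
    )
    paths["model_nln"] <- file.path(out_dir, "model_nln.json")
    write_ln_model(nln, paths["model_nln"])
    summary_row <- dplyr::bind_rows(
      dplyr::mutate(summary_row, model = "LN"),
      dplyr::bind_cols(glance(nln), glance(ffit))
    )
  }
  summary_row$config_hash <- config_hash(config)
  readr::write_csv(summary_row, paths["summary"])
  invisible(paths)
}

#' Run the slow-adaptation analysis and write its summary
#'
#' Bins and sorts trials, extracts per-pulse peaks from each bin-mean trace,
#' fits the peak decay (exponential for PN-like, linear for ORN-like
#' responses), computes the degree of adaptation across bins and writes one
#' CSV row per bin plus the summary.
#'
#' @param config A `run_config`.
#' @param trace_file Trace CSV.
#' @param stimulus_file Stimulus CSV (for the valve state).
#' @param out_dir Output directory.
#' @return Named vector of output paths, invisibly.
#' @export
run_adaptation <- function(config, trace_file, stimulus_file, out_dir = ".") {
  traces <- read_traces(trace_file)
  stim_df <- read_stimulus_csv(stimulus_file)
  valve <- tibble::tibble(
    time_s = stim_df$time_s,
    state = as.integer(stim_df$value > 0)
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ad <- config$adaptation
  kind <- if (config$truth$cell_type == "PN") "exponential" else "linear"
  binned <- bin_and_sort_trials(traces,
    sort_window = ad$sort_window, n_bins = ad$n_bins
  )
  rows <- purrr::map(split(binned, binned$bin), function(b) {
    pk <- extract_pulse_peaks(
      tibble::tibble(time_s = b$time_s, value = b$value),
      valve,
      latency = ad$latency
    )
    fit <- fit_peak_decay(pk,
      kind = kind, tau_cap = ad$tau_cap,
      t_end = max(valve$time_s), n_boot = 0
    )
    tibble::tibble(
      bin = b$bin[1], r0 = fit$r0, r_inf = fit$r_inf,
      tau = if (kind == "exponential") fit$params[["tau"]] else NA_real_,
      tau_at_cap = isTRUE(fit$tau_at_cap), n_pulses = fit$n
    )
  })
  per_bin <- dplyr::bind_rows(rows)
  summ <- degree_of_adaptation(per_bin)
  per_bin$config_hash <- config_hash(config)
  paths <- c(
    bins = file.path(out_dir, "adaptation_bins.csv"),
    summary = file.path(out_dir, "adaptation_summary.csv")
  )
  readr::write_csv(per_bin, paths["bins"])
  readr::write_csv(
    dplyr::mutate(glance(summ),
      d_lower = summ$ci95["lower"], d_upper = summ$ci95["upper"],
      config_hash = config_hash(config)
    ),
    paths["summary"]
  )
  invisible(paths)
}

#' Run the population analysis (PCA, rescaling, variance coding)
#'
#' Simulates ORN and PN populations from the configured glomerulus specs,
#' builds steady-state population matrices across the configured
#' concentrations, runs PCA, computes per-concentration CVs of PC1 scores and
#' the expected CV of the filtered stimulus, and writes
#' `population_pca.json` and `cv_report.json`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return Named vector of output paths, invisibly.
#' @export
run_population <- function(config = default_config(), out_dir = ".") {
  pop_cfg <- config$population
  if (pop_cfg$n_glomeruli < 1) {
    stop("config: empty glomerulus list", call. = FALSE)
  }
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stimulus
  valve <- valve_sequence(
    duration = st$duration, dt_update = st$dt_update, min_run = st$min_run,
    max_run = st$max_run, open_probability = st$open_probability,
    seed = config$seed, sample_rate = st$sample_rate
  )
  stimuli <- purrr::map(pop_cfg$concentrations, function(C) scale_stimulus(valve, C))
  specs <- population_specs(
    n_glomeruli = pop_cfg$n_glomeruli, d = pop_cfg$d,
    seed = config$seed,
    noise_frac = config$truth$noise_frac,
    trial_gain_sd = config$truth$trial_gain_sd,
    n_trials = config$truth$n_trials
  )
  orn <- simulate_population(stimuli, specs, cell_type = "ORN")
  mat <- build_population_matrix(orn,
    mode = pop_cfg$mode,
    discard_initial = config$estimator$discard_s
  )
  pca <- run_pca(mat, center = pop_cfg$center)
  cv <- compute_cv(pca$scores)
  ecv <- expected_cv(valve, tau_integration = pop_cfg$tau_integration)

  paths <- c(
    pca = file.path(out_dir, "population_pca.json"),
    cv = file.path(out_dir, "cv_report.json")
  )
  jsonlite::write_json(
    list(
      explained_variance_fraction = pca$explained_variance_fraction,
      loadings = as.data.frame(pca$loadings),
      center = pca$center, seed = config$seed,
      config_hash = config_hash(config)
    ),
    paths["pca"],
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      per_concentration = as.data.frame(tibble::as_tibble(cv)),
      expected_cv = as.numeric(ecv),
      tau_integration = pop_cfg$tau_integration,
      seed = config$seed, config_hash = config_hash(config)
    ),
    paths["cv"],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
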