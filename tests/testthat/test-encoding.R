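test_that("reverse correlation recovers a known exponential filter", {
  v <- valve_sequence(duration = 120, seed = 5)
  s <- scale_stimulus(v, 1)
  sim <- simulate_orn(s, linear_truth(tau = 0.5, seed = 5))
  filt <- estimate_filter(s, mean_trace(sim), n_lags = 80, ridge_lambda = 1e-8)
  truth <- eval_filter(filter_spec("k1", A1 = 1, tau1 = 0.5), filt$lag_s)
  cosine <- sum(filt$coef * truth) / sqrt(sum(filt$coef^2) * sum(truth^2))
  expect_gt(cosine, 0.999)
  expect_equal(sqrt(sum(filt$coef^2)), 1) # unit Euclidean norm
})

test_that("extreme ridge shrinks the filter to the degenerate flag", {
  v <- quick_valve(duration = 30, seed = 5)
  s <- scale_stimulus(v, 1)
  sim <- simulate_orn(s, linear_truth(tau = 0.5, seed = 5))
  filt <- estimate_filter(s, mean_trace(sim), ridge_lambda = 1e12)
  expect_true(attr(filt, "degenerate"))
  expect_lt(attr(filt, "scale"), 1e-6)
})

test_that("a biphasic generative filter yields a lagging negative lobe", {
  v <- valve_sequence(duration = 120, seed = 6)
  s <- scale_stimulus(v, 1)
  tru <- ground_truth(
    filter = filter_spec("k3", A1 = 1, tau1 = 0.3, A2 = -0.25, tau2 = 1.2),
    front_end = NULL, sensor = NULL, noise_frac = 0, trial_gain_sd = 0,
    n_trials = 1, seed = 6
  )
  sim <- simulate_pn(s, tru)
  filt <- estimate_filter(s, mean_trace(sim), ridge_lambda = 1e-8)
  i_pos <- which.max(filt$coef)
  i_neg <- which.min(filt$coef)
  expect_lt(filt$coef[i_neg], -0.01)
  expect_gt(i_neg, i_pos) # negative lobe comes after the positive one
})

test_that("filter estimation is shift-equivariant", {
  v <- valve_sequence(duration = 120, seed = 13)
  s <- scale_stimulus(v, 1)
  sim <- simulate_orn(s, linear_truth(tau = 0.4, seed = 13))
  resp <- mean_trace(sim)
  shift <- 5L # samples
  resp_shifted <- tibble::tibble(
    time_s = resp$time_s,
    value = dplyr::lag(resp$value, shift, default = 0)
  )
  f0 <- estimate_filter(s, resp, ridge_lambda = 1e-6)
  f1 <- estimate_filter(s, resp_shifted, ridge_lambda = 1e-6)
  expect_gt(
    sum(f1$coef[(shift + 1):80] * f0$coef[1:(80 - shift)]),
    0.99
  )
})

test_that("stimulus projection matches closed forms", {
  v <- quick_valve(duration = 20, seed = 1)
  s <- scale_stimulus(v, 1)
  zero <- scale_stimulus(valve_sequence(duration = 20, open_probability = 0, seed = 1), 1)
  dt <- 0.05
  delta <- structure(
    tibble::tibble(lag_s = (0:9) * dt, coef = c(1 / dt, rep(0, 9))),
    class = c("linear_filter", "tbl_df", "tbl", "data.frame")
  )
  expect_true(all(project_stimulus(zero, delta)$value == 0))
  pr <- project_stimulus(s, delta)
  expect_equal(pr$value, s$value, tolerance = 1e-12)
  expect_identical(sum(pr$burn_in), 9L)

  # unit step through exponential filter: 1 - exp(-t/tau)
  step <- scale_stimulus(
    valve_sequence(duration = 20, open_probability = 1, max_run = Inf, seed = 1), 1
  )
  tau <- 0.5
  expf <- tibble::tibble(
    lag_s = seq(0, 6, by = dt),
    coef = exp(-seq(0, 6, by = dt) / tau) / tau
  )
  pr2 <- project_stimulus(step, expf)
  t <- step$time_s
  analytic <- 1 - exp(-(t + dt) / tau)
  keep <- t > 0.5 & t < 12
  expect_lt(max(abs(pr2$value[keep] - analytic[keep])), 0.06) # discretisation error
})

test_that("static nonlinearity fits recover linear and Hill ground truth", {
  set.seed(2)
  x <- runif(600, -1, 3)
  lin <- fit_static_nonlinearity(x, 2 * x + 0.1, kind = "linear")
  expect_equal(unname(lin$coef["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(lin$coef["b"]), 0.1, tolerance = 1e-6)

  hill_y <- 2 * (x - min(x))^2 / ((x - min(x))^2 + 1.2^2)
  noisy <- hill_y + rnorm(length(x), 0, max(hill_y) / 10) # SNR 10
  hf <- fit_static_nonlinearity(x, noisy, kind = "hill")
  expect_equal(unname(hf$coef["H"]), 1.2, tolerance = 0.12)
  expect_equal(unname(hf$coef["n"]), 2, tolerance = 0.2)

  const <- fit_static_nonlinearity(x, rep(1.5, length(x)), kind = "linear")
  expect_equal(unname(const$coef["a"]), 0, tolerance = 1e-9)
  expect_equal(unname(const$coef["b"]), 1.5, tolerance = 1e-9)

  auto <- fit_static_nonlinearity(x, 2 * x + 0.1 + rnorm(600, 0, 0.05), kind = "auto")
  expect_identical(auto$kind, "linear") # BIC prefers 2 over 4 parameters
})

test_that("front-end Hill fits recover parameters and flag degeneracy", {
  concs <- 10^seq(-5.5, -2.5, length.out = 8)
  peaks <- 0.9 * concs^1.5 / (concs^1.5 + (1e-4)^1.5)
  fe <- fit_front_end_nl(tibble::tibble(concentration = concs, peak_response = peaks))
  expect_equal(unname(fe$coef["H"]), 1e-4, tolerance = 0.05 * 1e-4)
  expect_equal(unname(fe$coef["n"]), 1.5, tolerance = 0.05)
  # fitted curve monotone non-decreasing
  grid <- 10^seq(-6, -2, length.out = 50)
  expect_true(all(diff(eval_static_nonlinearity(fe, grid)) >= -1e-12))

  flat <- fit_front_end_nl(tibble::tibble(
    concentration = concs,
    peak_response = rep(0.5, 8)
  ))
  expect_true(isTRUE(flat$degenerate))
  expect_warning(
    fit_front_end_nl(tibble::tibble(
      concentration = concs,
      peak_response = rev(peaks)
    )),
    "monotone"
  )
  expect_error(fit_front_end_nl(tibble::tibble(
    concentration = concs[1:2],
    peak_response = peaks[1:2]
  )), "at least 3")
})

test_that("an identity cascade predicts the stimulus itself", {
  v <- quick_valve(duration = 20, seed = 2)
  s <- scale_stimulus(v, 1)
  dt <- 0.05
  model <- structure(
    list(
      filter = structure(
        tibble::tibble(lag_s = (0:9) * dt, coef = c(1 / dt, rep(0, 9))),
        class = c("linear_filter", "tbl_df", "tbl", "data.frame")
      ),
      nonlinearity = structure(
        list(kind = "linear", coef = c(a = 1, b = 0), shift = 0),
        class = "static_nonlinearity"
      ),
      front_end = NULL, nr = NA_real_,
      split = list(discard_s = 0, train_fraction = 2 / 3, onset_s = 0, eval_from = 10),
      stimulus = s
    ),
    class = "ln_model"
  )
  pred <- predict(model, s)
  expect_equal(pred$value, s$value, tolerance = 1e-12)
})

test_that("fitted LN models predict held-out data within the noise (NR < 1)", {
  v <- valve_sequence(duration = 90, seed = 3)
  s <- scale_stimulus(v, 1e-4)
  sim <- simulate_orn(s, orn_truth(seed = 3))
  m <- fit_ln(s, sim, discard_s = 20, ridge_lambda = 1e-2)
  expect_lt(m$nr, 1)
  expect_equal(evaluate_nr(m, sim), m$nr)
  g <- glance(m)
  expect_identical(g$model, "LN")
  expect_identical(nrow(tidy(m)), length(m$nonlinearity$coef))
})

test_that("NLN with an identity front end reproduces the LN model exactly", {
  v <- valve_sequence(duration = 60, seed = 8)
  s <- scale_stimulus(v, 1e-4)
  sim <- simulate_orn(s, orn_truth(seed = 8))
  identity_fe <- structure(
    list(kind = "linear", coef = c(a = 1, b = 0), shift = 0),
    class = "static_nonlinearity"
  )
  ln <- fit_ln(s, sim, discard_s = 20, ridge_lambda = 1e-2)
  nln <- fit_ln(s, sim, discard_s = 20, ridge_lambda = 1e-2, front_end = identity_fe)
  expect_equal(nln$filter$coef, ln$filter$coef, tolerance = 1e-10)
  expect_equal(predict(nln)$value, predict(ln)$value, tolerance = 1e-10)
  expect_identical(glance(nln)$model, "NLN")
})

test_that("the NR statistic has its defining properties", {
  tm <- seq(0, 10, by = 0.05)
  set.seed(4)
  truth <- sin(tm) + 2
  trials <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(time_s = tm, value = truth + rnorm(length(tm), 0, 0.3), trial_id = i)
  })
  avg <- average_trials(trials)
  # prediction identical to the trial mean: P_R = 0 -> NR = 0
  expect_equal(nr_statistic(avg$mean, trials), 0)
  # prediction equal to the noiseless truth: NR is about 1/(n-1)
  nr <- nr_statistic(truth, trials)
  expect_lt(nr, 1)
  expect_lt(abs(nr - 1 / 3) / (1 / 3), 1)

  same <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(time_s = tm, value = truth, trial_id = i)
  })
  expect_error(nr_statistic(truth, same), "zero")
})

test_that("NR decreases statistically with trial count", {
  tm <- seq(0, 30, by = 0.05)
  truth <- sin(tm) + 2
  nr_for <- function(n, seed) {
    set.seed(seed)
    trials <- purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(time_s = tm, value = truth + rnorm(length(tm), 0, 0.3), trial_id = i)
    })
    nr_statistic(truth, trials)
  }
  nr3 <- mean(vapply(1:5, function(s) nr_for(3, s), numeric(1)))
  nr11 <- mean(vapply(1:5, function(s) nr_for(11, s + 50), numeric(1)))
  expect_gt(nr3, nr11)
})

test_that("response gain follows the slope of the static function", {
  lin <- structure(
    list(kind = "linear", coef = c(a = 3, b = 0.4), shift = 0),
    class = "static_nonlinearity"
  )
  expect_equal(response_gain(lin), 3)

  hill <- structure(
    list(kind = "hill", coef = c(f0 = 0, f_max = 2, H = 0.5, n = 1), shift = 0),
    class = "static_nonlinearity"
  )
  # for n = 1 the maximum slope over [0, 4H] is at x -> 0: f_max/H... but the
  # derivative at x = H is n*f_max/(4H); verify numerically over a window at H
  g_at_H <- response_gain(hill, range = c(0.5, 0.500001))
  expect_equal(g_at_H, 1 * 2 / (4 * 0.5), tolerance = 1e-3)

  hill2 <- hill
  hill2$coef["f_max"] <- 4
  expect_equal(
    response_gain(hill2, range = c(0.5, 0.500001)),
    2 * response_gain(hill, range = c(0.5, 0.500001))
  )
})

test_that("LN models serialize to JSON with filter and split metadata", {
  v <- quick_valve(duration = 40, seed = 9)
  s <- scale_stimulus(v, 1e-4)
  sim <- simulate_orn(s, orn_truth(seed = 9))
  m <- fit_ln(s, sim, discard_s = 10, ridge_lambda = 1e-2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ln_model(m, path)
  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$model, "LN")
  expect_equal(length(parsed$filter$coef), nrow(m$filter))
  expect_equal(parsed$nr, m$nr, tolerance = 1e-12)
})
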