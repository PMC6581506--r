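#' Extract per-pulse peak responses
#'
#' For every maximal valve-open run, finds the maximum response between the
#' run onset and the run offset plus `latency` (the peak-search window is
#' extended past valve closure to cover indicator lag).
#'
#' @param response Trace tibble (`time_s`, `value`) on a grid compatible with
#'   the valve.
#' @param valve A [valve_sequence()].
#' @param latency Window extension past valve closure, seconds (default 0.3).
#' @param smooth_s Optional Gaussian pre-smoothing sd in seconds applied to
#'   the response before peak picking (reduces the upward bias of max-based
#'   peaks on noisy traces; 0 = none).
#' @return A tibble of class `pulse_peaks` with columns `pulse`, `onset_s`,
#'   `duration_s`, `peak` and `peak_time_s` (the time at which the maximum
#'   occurred — the moment at which the peak samples any slow gain change).
#' @export
extract_pulse_peaks <- function(response, valve, latency = 0.3, smooth_s = 0) {
  assert_columns(response, c("time_s", "value"), "response")
  if (smooth_s > 0) {
    response <- tibble::tibble(
      time_s = response$time_s,
      value = gaussian_smooth(response$value, smooth_s, grid_dt(response$time_s))
    )
  }
  runs <- valve_runs(valve)
  open <- runs[runs$state == 1, ]
  if (nrow(open) == 0) stop("valve has no open runs", call. = FALSE)
  peaks <- purrr::pmap_dfr(
    list(open$onset_s, open$offset_s),
    function(on, off) {
      w <- which(response$time_s >= on - 1e-9 &
        response$time_s <= off + latency + 1e-9)
      if (!length(w)) {
        return(tibble::tibble(peak = NA_real_, peak_time_s = NA_real_))
      }
      i <- w[which.max(response$value[w])]
      tibble::tibble(peak = response$value[i], peak_time_s = response$time_s[i])
    }
  )
  out <- tibble::tibble(
    pulse = seq_len(nrow(open)),
    onset_s = open$onset_s,
    duration_s = open$duration_s,
    peak = peaks$peak,
    peak_time_s = peaks$peak_time_s
  )
  out <- out[!is.na(out$peak), ]
  structure(out, class = c("pulse_peaks", class(out)))
}

#' Pool, sort and bin trials by response amplitude
#'
#' Trials are sorted by their maximum response within the first
#' `sort_window` seconds and binned into `n_bins` equal-width bins between
#' zero and the largest maximum; trials within a bin are averaged. Empty bins
#' are dropped with a message.
#'
#' @param trials Long tibble (`time_s`, `value`, `trial_id`).
#' @param sort_window Sorting window in seconds (default 12).
#' @param n_bins Number of amplitude bins (default 10).
#' @return A long tibble with columns `bin`, `bin_mid`, `time_s`, `value`
#'   (bin-mean trace) and `n_trials`.
#' @export
bin_and_sort_trials <- function(trials, sort_window = 12, n_bins = 10) {
  assert_columns(trials, c("time_s", "value", "trial_id"), "trials")
  maxima <- dplyr::summarise(
    dplyr::group_by(trials, .data$trial_id),
    max_resp = max(.data$value[.data$time_s <= sort_window]),
    .groups = "drop"
  )
  top <- max(maxima$max_resp)
  if (top <= 0) stop("all responses are non-positive in the sort window", call. = FALSE)
  breaks <- seq(0, top, length.out = n_bins + 1)
  maxima$bin <- pmin(
    pmax(findInterval(maxima$max_resp, breaks, rightmost.closed = TRUE), 1L),
    n_bins
  )
  joined <- dplyr::left_join(trials, maxima[c("trial_id", "bin")], by = "trial_id")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$bin, .data$time_s),
    value = mean(.data$value), n_trials = dplyr::n_distinct(.data$trial_id),
    .groups = "drop"
  )
  occupied <- sort(unique(out$bin))
  if (length(occupied) < n_bins) {
    message(sprintf("%d of %d bins empty; dropped", n_bins - length(occupied), n_bins))
  }
  out$bin_mid <- (breaks[out$bin] + breaks[out$bin + 1]) / 2
  dplyr::relocate(out, "bin", "bin_mid")
}

#' Fit the decay of pulse peaks over time
#'
#' Linear fit \eqn{r_m(t) = A + B t} (sustained/ORN-like responses) or
#' exponential fit \eqn{r_m(t) = A + B e^{-t/\tau}} (adapting/PN-like
#' responses) to the per-pulse peak series. The exponential timescale is
#' constrained to at most `tau_cap` (40 s); fits that pin the timescale at
#' the cap are flagged. The initial and adapted responses are derived from
#' the fitted parameters: exponential, \eqn{r_0 = A + B}, \eqn{r_\infty = A};
#' linear, \eqn{r_0 = A}, \eqn{r_\infty = A + B\,T_{end}}.
#'
#' @param peaks A [extract_pulse_peaks()] result (or tibble with `onset_s`,
#'   `peak`).
#' @param kind `"exponential"` or `"linear"`.
#' @param t_end Evaluation point of the adapted response for the linear fit
#'   (default 120 s, the record end).
#' @param tau_cap Maximum timescale, seconds.
#' @param n_boot Parametric-bootstrap resamples for the 95% CIs (default 200;
#'   0 disables the bootstrap and keeps the local-covariance CIs only).
#' @param seed Seed for the bootstrap.
#' @return An object of class `adaptation_fit`: list with `kind`, `params`,
#'   `r0`, `r_inf`, `ci95`, `tau_at_cap`, `n`.
#' @export
fit_peak_decay <- function(peaks, kind = c("exponential", "linear"),
                           t_end = 120, tau_cap = 40, n_boot = 200,
                           seed = NULL) {
  kind <- match.arg(kind)
  assert_columns(peaks, c("onset_s", "peak"), "peaks")
  t <- if ("peak_time_s" %in% names(peaks)) peaks$peak_time_s else peaks$onset_s
  y <- peaks$peak
  if (kind == "linear" && length(y) < 4) {
    stop("linear fit needs at least 4 pulses", call. = FALSE)
  }
  if (kind == "exponential" && length(y) < 5) {
    stop("exponential fit needs at least 5 pulses", call. = FALSE)
  }
  if (all(abs(y) < 1e-300)) stop("degenerate (all-zero) peaks", call. = FALSE)

  fit_once <- function(t, y) {
    if (kind == "linear") {
      fit <- stats::lm(y ~ t)
      p <- c(A = unname(stats::coef(fit)[1]), B = unname(stats::coef(fit)[2]))
      list(
        params = p, vcov = suppressWarnings(stats::vcov(fit)),
        resid = stats::residuals(fit)
      )
    } else {
      if (stats::sd(y) < 1e-12 * max(abs(y))) {
        # constant peaks: no decay; the timescale is unidentifiable
        return(list(
          params = c(A = mean(y), B = 0, tau = NA_real_),
          vcov = NULL, resid = y - mean(y)
        ))
      }
      best <- NULL
      for (tau0 in c(1, 3, 8, 20, 40)) {
        f <- tryCatch(
          minpack.lm::nlsLM(y ~ A + B * exp(-t / tau),
            start = list(A = min(y), B = max(y) - min(y), tau = tau0),
            lower = c(A = -Inf, B = -Inf, tau = 1e-3),
            upper = c(A = Inf, B = Inf, tau = tau_cap),
            control = minpack.lm::nls.lm.control(maxiter = 300)
          ),
          error = function(e) NULL
        )
        if (!is.null(f)) {
          rss <- sum(stats::residuals(f)^2)
          if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
        }
      }
      if (is.null(best)) stop("exponential peak-decay fit failed", call. = FALSE)
      p <- stats::coef(best$fit)
      list(
        params = c(A = unname(p["A"]), B = unname(p["B"]), tau = unname(p["tau"])),
        vcov = tryCatch(stats::vcov(best$fit), error = function(e) NULL),
        resid = stats::residuals(best$fit)
      )
    }
  }
  base <- fit_once(t, y)
  p <- base$params
  r0 <- if (kind == "exponential") p[["A"]] + p[["B"]] else p[["A"]]
  r_inf <- if (kind == "exponential") p[["A"]] else p[["A"]] + p[["B"]] * t_end
  tau_at_cap <- kind == "exponential" && !is.na(p[["tau"]]) &&
    p[["tau"]] > 0.99 * tau_cap

  ci <- NULL
  if (!is.null(base$vcov)) {
    se <- sqrt(pmax(diag(base$vcov), 0))
    ci <- cbind(lower = p - 1.96 * se, upper = p + 1.96 * se)
  }
  boot <- NULL
  if (n_boot > 0) {
    sd_res <- stats::sd(base$resid)
    fitted_y <- y - base$resid
    boot_params <- with_seed_or_not(seed, {
      purrr::map(seq_len(n_boot), function(i) {
        yb <- fitted_y + stats::rnorm(length(y), 0, sd_res)
        tryCatch(fit_once(t, yb)$params, error = function(e) NULL)
      })
    })
    boot_params <- do.call(rbind, boot_params[!vapply(boot_params, is.null, logical(1))])
    if (!is.null(boot_params) && nrow(boot_params) >= 20) {
      boot <- apply(boot_params, 2, stats::quantile, probs = c(0.025, 0.975))
      ci <- cbind(lower = boot[1, names(p)], upper = boot[2, names(p)])
    }
  }
  structure(
    list(
      kind = kind, params = p, r0 = r0, r_inf = r_inf, ci95 = ci,
      tau_at_cap = tau_at_cap, tau_cap = tau_cap, n = length(y),
      t_end = t_end
    ),
    class = "adaptation_fit"
  )
}

#' Degree of adaptation from initial/adapted response pairs
#'
#' Ordinary least squares of the adapted response on the initial response,
#' \eqn{r_\infty = a + b\, r_0}; the degree of adaptation is \eqn{d = 1 - b}
#' (0 = no adaptation, 1 = complete adaptation). Values outside `[0, 1]` are
#' flagged, not clipped.
#'
#' @param pairs A tibble with columns `r0` and `r_inf` (>= 2 rows spanning a
#'   nonzero `r0` range).
#' @return An object of class `adaptation_summary`: list with `d`, `slope`,
#'   `intercept`, `ci95` (on `d`), `out_of_range` flag and the input pairs.
#' @export
degree_of_adaptation <- function(pairs) {
  assert_columns(pairs, c("r0", "r_inf"), "pairs")
  if (nrow(pairs) < 2) stop("need at least 2 (r0, r_inf) pairs", call. = FALSE)
  if (stats::sd(pairs$r0) < 1e-300) {
    stop("r0 values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(r_inf ~ r0, data = pairs)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  se_b <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[2])
  d <- 1 - b
  ci <- c(lower = d - 1.96 * se_b, upper = d + 1.96 * se_b)
  structure(
    list(
      d = d, slope = b, intercept = a, ci95 = ci,
      out_of_range = d < 0 || d > 1, pairs = pairs, n = nrow(pairs)
    ),
    class = "adaptation_summary"
  )
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(
    "<adaptation_fit>", x$kind, "|",
    paste(names(x$params), format(x$params, digits = 3), sep = "=", collapse = " "),
    "| r0=", format(x$r0, digits = 3), "r_inf=", format(x$r_inf, digits = 3),
    if (isTRUE(x$tau_at_cap)) "| tau at cap", "\n"
  )
  invisible(x)
}

#' @export
print.adaptation_summary <- function(x, ...) {
  cat(
    "<adaptation_summary> d =", format(x$d, digits = 3),
    sprintf("[%.3f, %.3f]", x$ci95[1], x$ci95[2]),
    "from", x$n, "pairs\n"
  )
  invisible(x)
}

#' Tidy methods for adaptation fits and summaries
#'
#' @param x,... An `adaptation_fit` or `adaptation_summary`.
#' @return A tibble of parameter estimates (with CIs when available).
#' @method tidy adaptation_fit
#' @export
tidy.adaptation_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$params), estimate = unname(x$params))
  if (!is.null(x$ci95)) {
    out$conf.low <- x$ci95[, "lower"]
    out$conf.high <- x$ci95[, "upper"]
  }
  out
}

#' @rdname tidy.adaptation_fit
#' @method tidy adaptation_summary
#' @export
tidy.adaptation_summary <- function(x, ...) {
  tibble::tibble(
    term = c("d", "slope", "intercept"),
    estimate = c(x$d, x$slope, x$intercept),
    conf.low = c(x$ci95["lower"], NA, NA),
    conf.high = c(x$ci95["upper"], NA, NA)
  )
}

#' @rdname tidy.adaptation_fit
#' @method glance adaptation_summary
#' @export
glance.adaptation_summary <- function(x, ...) {
  tibble::tibble(d = x$d, slope = x$slope, n = x$n, out_of_range = x$out_of_range)
}

#' Joint multiplicative fit of the degree of adaptation across conditions
#'
#' Fits the shared slow-depression gain trajectory
#' \eqn{g(t) = (1-d) + d\,e^{-t/\tau}} directly to several per-condition
#' pulse-peak series at once, modelling each series as
#' \eqn{r_m(t) = \bar a_c\, g(t)}: the per-condition amplitudes
#' \eqn{\bar a_c} are profiled out analytically, so only \eqn{(d, \tau)} are
#' optimised. This pools all pulses of all conditions into one estimate of
#' `d` and avoids the variance of extrapolating separate per-condition
#' exponential fits back to stimulus onset. Negative `d` (facilitation) is
#' allowed so that estimates near zero are not truncated at the boundary;
#' the timescale is kept above the fast filter/sensor timescales so the
#' slow gain is not confused with the response onset.
#'
#' @param peak_series A list of [extract_pulse_peaks()] results (or tibbles
#'   with `onset_s`, `peak`), one per condition (e.g. concentration).
#' @param tau_bounds Bounds on the adaptation timescale, seconds.
#' @param d_bounds Bounds on the degree of adaptation.
#' @return An object of class `adaptation_joint_fit`: list with `d`, `tau`,
#'   `amplitudes` (per condition), `rss`, `n`.
#' @export
fit_adaptation_joint <- function(peak_series, tau_bounds = c(3, 40),
                                 d_bounds = c(-1, 1)) {
  stopifnot(length(peak_series) >= 1)
  peak_series <- purrr::map(peak_series, function(s) {
    assert_columns(s, c("onset_s", "peak"), "peak series")
    s
  })
  times <- purrr::map(peak_series, function(s) {
    if ("peak_time_s" %in% names(s)) s$peak_time_s else s$onset_s
  })
  profile_rss <- function(d, tau) {
    sum(purrr::map2_dbl(peak_series, times, function(s, t) {
      g <- (1 - d) + d * exp(-t / tau)
      a <- sum(s$peak * g) / sum(g^2)
      sum((s$peak - a * g)^2)
    }))
  }
  obj <- function(par) profile_rss(par[1], exp(par[2]))
  best <- NULL
  for (d0 in c(-0.3, 0.05, 0.3, 0.6, 0.9)) {
    for (tau0 in c(4, 8, 20)) {
      o <- stats::optim(c(d0, log(tau0)), obj,
        method = "L-BFGS-B",
        lower = c(d_bounds[1], log(tau_bounds[1])),
        upper = c(d_bounds[2], log(tau_bounds[2]))
      )
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  d <- best$par[1]
  tau <- exp(best$par[2])
  amps <- purrr::map2_dbl(peak_series, times, function(s, t) {
    g <- (1 - d) + d * exp(-t / tau)
    sum(s$peak * g) / sum(g^2)
  })
  structure(
    list(
      d = d, tau = tau, amplitudes = amps, rss = best$value,
      n = sum(vapply(peak_series, nrow, integer(1)))
    ),
    class = "adaptation_joint_fit"
  )
}

#' @export
print.adaptation_joint_fit <- function(x, ...) {
  cat(
    "<adaptation_joint_fit> d =", format(x$d, digits = 3),
    " tau =", format(x$tau, digits = 3), "s over", length(x$amplitudes),
    "conditions (", x$n, "pulses )\n"
  )
  invisible(x)
}

#' @rdname tidy.adaptation_fit
#' @method tidy adaptation_joint_fit
#' @export
tidy.adaptation_joint_fit <- function(x, ...) {
  tibble::tibble(
    term = c("d", "tau", paste0("amplitude_", seq_along(x$amplitudes))),
    estimate = c(x$d, x$tau, unname(x$amplitudes))
  )
}
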