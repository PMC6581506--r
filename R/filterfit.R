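#' Fit a parametric exponential-family model to a linear filter
#'
#' Nonlinear least squares of one of the three filter families (see
#' [filter_spec()]) to a sampled filter, with timescales bounded to
#' `[0.05, 40]` s, multi-start initialisation over a log-spaced timescale
#' grid, and 95% confidence intervals from the local covariance.
#'
#' @param filter A `linear_filter` (tibble with `lag_s`, `coef`) of at least
#'   10 lag points.
#' @param family `"k1"`, `"k2"` or `"k3"`.
#' @param tau_bounds Timescale bounds in seconds.
#' @param tau_starts Multi-start grid for timescales.
#' @return An object of class `filter_fit`: list with `family`, `params`,
#'   `sigma2`, `n`, `k` (free-parameter count), `bic`, `ci95`, `fitted`,
#'   `perfect_fit` flag.
#' @export
fit_parametric <- function(filter, family = c("k1", "k2", "k3"),
                           tau_bounds = c(0.05, 40),
                           tau_starts = c(0.1, 0.3, 1, 3, 10)) {
  family <- match.arg(family)
  assert_columns(filter, c("lag_s", "coef"), "filter")
  if (nrow(filter) < 10) stop("filter needs at least 10 lag points", call. = FALSE)
  t <- filter$lag_s
  y <- filter$coef
  a0 <- y[which.max(abs(y))]
  k_free <- c(k1 = 2L, k2 = 3L, k3 = 4L)[[family]]

  best <- NULL
  try_fit <- function(start, lower, upper, formula) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula,
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <<- list(fit = fit, rss = rss)
    }
  }
  if (family == "k1") {
    for (tau0 in tau_starts) {
      try_fit(
        list(A1 = a0, tau1 = tau0),
        c(A1 = -Inf, tau1 = tau_bounds[1]), c(A1 = Inf, tau1 = tau_bounds[2]),
        y ~ A1 * exp(-t / tau1)
      )
    }
  } else if (family == "k2") {
    for (tau0 in tau_starts) {
      try_fit(
        list(A1 = a0, tau1 = tau0, A2 = 0),
        c(A1 = -Inf, tau1 = tau_bounds[1], A2 = -Inf),
        c(A1 = Inf, tau1 = tau_bounds[2], A2 = Inf),
        y ~ A1 * exp(-t / tau1) + A2
      )
    }
  } else {
    for (tau0 in tau_starts) {
      for (mult in c(4, 10, 30)) {
        tau20 <- min(tau0 * mult, tau_bounds[2])
        try_fit(
          list(A1 = a0, tau1 = tau0, A2 = -0.1 * a0, tau2 = tau20),
          c(A1 = -Inf, tau1 = tau_bounds[1], A2 = -Inf, tau2 = tau_bounds[1]),
          c(A1 = Inf, tau1 = tau_bounds[2], A2 = Inf, tau2 = tau_bounds[2]),
          y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
        )
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf("all starts failed to converge for family %s", family),
      call. = FALSE
    )
  }
  fit <- best$fit
  params <- stats::coef(fit)
  # enforce tau1 < tau2 labelling for k3
  if (family == "k3" && params["tau1"] > params["tau2"]) {
    params <- params[c("A2", "tau2", "A1", "tau1")]
    names(params) <- c("A1", "tau1", "A2", "tau2")
  }
  n <- length(y)
  sigma2 <- best$rss / n
  perfect <- sigma2 < 1e-300
  ci <- tryCatch(
    {
      se <- sqrt(diag(stats::vcov(fit)))
      cbind(
        lower = stats::coef(fit) - 1.96 * se,
        upper = stats::coef(fit) + 1.96 * se
      )
    },
    error = function(e) NULL
  )
  structure(
    list(
      family = family, params = params, sigma2 = sigma2, n = n, k = k_free,
      bic = if (perfect) -Inf else n * log(sigma2) + k_free * log(n),
      ci95 = ci, fitted = stats::fitted(fit), lag_s = t,
      perfect_fit = perfect
    ),
    class = "filter_fit"
  )
}

#' BIC of a parametric filter fit
#'
#' \eqn{BIC = n \ln \sigma^2 + k \ln n} with \eqn{\sigma^2} the mean squared
#' residual and k the number of free parameters (k1: 2, k2: 3, k3: 4). A
#' perfect fit (\eqn{\sigma^2 = 0}) returns `-Inf` with the `perfect_fit`
#' flag set on the fit object.
#'
#' @param object A `filter_fit`.
#' @param ... Unused.
#' @return Scalar BIC.
#' @export
BIC.filter_fit <- function(object, ...) {
  object$bic
}

#' Select the best parametric filter family by BIC
#'
#' Fits all requested families and returns the fit with the lowest BIC; ties
#' are broken toward fewer parameters. Families that fail to converge are
#' dropped with a warning.
#'
#' @param filter A `linear_filter`.
#' @param families Families to consider.
#' @param ... Passed to [fit_parametric()].
#' @return The winning `filter_fit`, with all per-family BICs in
#'   `$bic_all`.
#' @export
select_filter_model <- function(filter, families = c("k1", "k2", "k3"), ...) {
  fits <- purrr::map(families, function(fam) {
    tryCatch(fit_parametric(filter, fam, ...), error = function(e) {
      warning(sprintf("family %s failed: %s", fam, conditionMessage(e)))
      NULL
    })
  })
  names(fits) <- families
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("all filter families failed to fit", call. = FALSE)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(bics, ks) # ties toward fewer parameters
  best <- fits[[ord[1]]]
  best$bic_all <- bics
  best
}

#' Calcium-sensor kinetic model
#'
#' A first-order (unit-area exponential) kernel describing the fluorescence
#' sensor's kinetics: GCaMP3 has a slower timescale (0.7 s) than GCaMP6f
#' (0.2 s). The unit-area normalisation preserves steady-state amplitudes.
#'
#' @param sensor `"GCaMP3"`, `"GCaMP6f"` or `"custom"`.
#' @param tau Timescale in seconds; required for `"custom"`, otherwise the
#'   sensor default.
#' @return An object of class `sensor_model` with elements `sensor`, `tau`.
#' @export
sensor_model <- function(sensor = c("GCaMP3", "GCaMP6f", "custom"), tau = NULL) {
  sensor <- match.arg(sensor)
  tau <- tau %||% switch(sensor,
    GCaMP3 = 0.7,
    GCaMP6f = 0.2,
    custom = stop("custom sensor needs tau", call. = FALSE)
  )
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(list(sensor = sensor, tau = tau), class = "sensor_model")
}

#' Convolve a signal with sensor kinetics
#'
#' Causal convolution with the unit-area exponential kernel of the sensor
#' (exact first-order-hold discretisation, so constant inputs are preserved
#' exactly at steady state).
#'
#' @param trace A tibble with `time_s`, `value` on a uniform grid.
#' @param sensor A [sensor_model()].
#' @return The convolved trace tibble.
#' @export
convolve_with_sensor <- function(trace, sensor) {
  assert_columns(trace, c("time_s", "value"), "trace")
  stopifnot(inherits(sensor, "sensor_model"))
  dt <- grid_dt(trace$time_s)
  tibble::tibble(time_s = trace$time_s, value = exp_conv(trace$value, sensor$tau, dt))
}

#' Deconvolve sensor kinetics from a trace
#'
#' Inverts the first-order sensor kernel in the time domain. The sensor
#' convolution is the exact discretisation of \eqn{\tau y' + y = x} for
#' piecewise-linear input, and the deconvolution inverts that recursion
#' algebraically — the discrete counterpart of \eqn{x(t) = y(t) + \tau\,dy/dt}
#' — so a convolve/deconvolve round trip is exact to machine precision.
#' Optional Gaussian pre-smoothing (`smoothing` seconds) controls the
#' high-frequency noise that deconvolution amplifies in measured data.
#'
#' @param trace A tibble with `time_s`, `value` on a uniform grid.
#' @param sensor A [sensor_model()]; `tau` must exceed the sample interval.
#' @param smoothing Gaussian smoothing sd in seconds (0 = none).
#' @return The deconvolved trace tibble.
#' @export
deconvolve_sensor <- function(trace, sensor, smoothing = 0) {
  assert_columns(trace, c("time_s", "value"), "trace")
  stopifnot(inherits(sensor, "sensor_model"))
  dt <- grid_dt(trace$time_s)
  if (sensor$tau <= dt) {
    stop("sensor tau must exceed the sample interval (inverse ill-posed)",
      call. = FALSE
    )
  }
  v <- trace$value
  if (smoothing > 0) v <- gaussian_smooth(v, smoothing, dt)
  tibble::tibble(time_s = trace$time_s, value = exp_deconv(v, sensor$tau, dt))
}

#' @export
print.filter_fit <- function(x, ...) {
  cat(
    "<filter_fit>", x$family, " BIC=", format(x$bic, digits = 5), "\n  ",
    paste(names(x$params), format(x$params, digits = 4),
      sep = "=", collapse = "  "
    ), "\n"
  )
  invisible(x)
}

#' Tidy and glance methods for parametric filter fits
#'
#' @param x,... A `filter_fit`; further arguments ignored.
#' @return `tidy()`: one row per parameter with 95% CI; `glance()`: one-row
#'   summary with family, sigma2, n, k and BIC.
#' @method tidy filter_fit
#' @export
tidy.filter_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params)
  )
  if (!is.null(x$ci95)) {
    idx <- match(out$term, rownames(x$ci95))
    out$conf.low <- x$ci95[idx, "lower"]
    out$conf.high <- x$ci95[idx, "upper"]
  }
  out
}

#' @rdname tidy.filter_fit
#' @method glance filter_fit
#' @export
glance.filter_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, sigma2 = x$sigma2, n = x$n, k = x$k, bic = x$bic,
    perfect_fit = x$perfect_fit
  )
}

#' Serialize a parametric filter fit to JSON
#'
#' @param fit A `filter_fit` (ideally from [select_filter_model()], so that
#'   all per-family BICs are included).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_fit <- function(fit, path) {
  obj <- list(
    family = fit$family, params = as.list(fit$params),
    sigma2 = fit$sigma2, n = fit$n, k = fit$k, bic = fit$bic,
    bic_all = as.list(fit$bic_all %||% stats::setNames(fit$bic, fit$family)),
    ci95 = if (!is.null(fit$ci95)) {
      apply(fit$ci95, 1, as.list, simplify = FALSE)
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
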