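#' Estimate a linear filter by ridge-regularised reverse correlation
#'
#' Solves \eqn{(S^\top S + \lambda I)k = S^\top r} over a causal lag window,
#' where the design matrix S holds the stimulus at lags 0 ... `n_lags`-1
#' samples. Stimulus and response are mean-subtracted before estimation. The
#' filter is rescaled to unit Euclidean norm with its sign chosen so the
#' dominant (largest-magnitude, earliest on ties) lobe is positive.
#'
#' @param stimulus A `stimulus_trace` (or tibble with `time_s`, `value`).
#' @param response A trace tibble on the same grid (`time_s`, `value`).
#' @param n_lags Number of causal lags (default 80: a 4 s filter at 20 Hz).
#' @param ridge_lambda Ridge penalty; `NULL` selects it by 5-fold blocked
#'   cross-validation on a log-spaced grid.
#' @param subset Optional logical vector marking response samples to use as
#'   regression rows (e.g. a training segment); lagged stimulus history may
#'   extend outside it.
#' @return A tibble of class `linear_filter` with columns `lag_s`, `coef`
#'   and estimation metadata in attributes (`ridge_lambda`, `n_lags`,
#'   `sample_rate`, `scale` = pre-normalisation norm, `degenerate`).
#' @export
estimate_filter <- function(stimulus, response, n_lags = 80,
                            ridge_lambda = NULL, subset = NULL) {
  assert_columns(stimulus, c("time_s", "value"), "stimulus")
  assert_columns(response, c("time_s", "value"), "response")
  if (nrow(stimulus) != nrow(response) ||
    max(abs(stimulus$time_s - response$time_s)) > 1e-9) {
    stop("stimulus and response must share the time grid", call. = FALSE)
  }
  n <- nrow(stimulus)
  if (n_lags >= n) stop("n_lags must be smaller than the record length", call. = FALSE)
  dt <- grid_dt(stimulus$time_s)
  s <- stimulus$value - mean(stimulus$value)
  r <- response$value - mean(response$value)
  X <- stats::embed(s, n_lags) # row t: s[t], s[t-1], ..., s[t-n_lags+1]
  y <- r[n_lags:n]
  if (!is.null(subset)) {
    keep <- subset[n_lags:n]
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (nrow(X) <= n_lags) stop("record too short for the requested lags", call. = FALSE)

  scale_ref <- mean(colSums(X^2)) # lambda is expressed relative to this
  if (is.null(ridge_lambda)) {
    ridge_lambda <- select_ridge_lambda(X, y, scale_ref)
  }
  if (ridge_lambda < 0) stop("ridge_lambda must be non-negative", call. = FALSE)
  XtX <- crossprod(X)
  beta <- tryCatch(
    solve(XtX + ridge_lambda * scale_ref * diag(n_lags), crossprod(X, y)),
    error = function(e) {
      stop("singular design matrix; increase ridge_lambda", call. = FALSE)
    }
  )
  k <- as.numeric(beta) / dt
  nrm <- sqrt(sum(k^2))
  degenerate <- nrm < 1e-10
  if (!degenerate) {
    k <- k / nrm
    peak <- which.max(abs(k))
    if (k[peak] < 0) k <- -k
  }
  out <- tibble::tibble(lag_s = (seq_len(n_lags) - 1L) * dt, coef = k)
  structure(out,
    class = c("linear_filter", class(out)),
    ridge_lambda = ridge_lambda, n_lags = n_lags, sample_rate = 1 / dt,
    scale = nrm, degenerate = degenerate
  )
}

# 5-fold blocked cross-validation over a log grid of relative penalties.
select_ridge_lambda <- function(X, y, scale_ref,
                                grid = 10^seq(-8, 0, by = 1), folds = 5) {
  n <- nrow(X)
  p <- ncol(X)
  block <- cut(seq_len(n), folds, labels = FALSE)
  err <- vapply(grid, function(lam) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- block != f
      Xt <- X[tr, , drop = FALSE]
      bt <- tryCatch(
        solve(crossprod(Xt) + lam * scale_ref * diag(p), crossprod(Xt, y[tr])),
        error = function(e) NULL
      )
      if (is.null(bt)) {
        return(Inf)
      }
      pred <- X[!tr, , drop = FALSE] %*% bt
      se <- se + sum((y[!tr] - pred)^2)
    }
    se
  }, numeric(1))
  grid[which.min(err)]
}

#' Project a stimulus onto a linear filter
#'
#' Causal discrete convolution of the stimulus with the filter, scaled by the
#' sample interval: \eqn{s_{pr}(t) = \sum_j k_j s(t - j\,dt)\, dt}. The first
#' `n_lags - 1` samples lack full stimulus history and are flagged as burn-in.
#'
#' @param stimulus A `stimulus_trace` (columns `time_s`, `value`).
#' @param filter A [estimate_filter()] result (columns `lag_s`, `coef`).
#' @return A tibble `time_s`, `value`, `burn_in`.
#' @export
project_stimulus <- function(stimulus, filter) {
  assert_columns(stimulus, c("time_s", "value"), "stimulus")
  assert_columns(filter, c("lag_s", "coef"), "filter")
  dt <- grid_dt(stimulus$time_s)
  proj <- causal_conv(stimulus$value, filter$coef, dt)
  burn <- seq_len(nrow(stimulus)) < nrow(filter)
  tibble::tibble(time_s = stimulus$time_s, value = proj, burn_in = burn)
}

#' Fit a static nonlinearity to projected stimulus vs response
#'
#' Least-squares fit of either a linear function \eqn{f(x) = a x + b} or a
#' Hill function \eqn{f(x) = f_0 + f_{max} x'^n / (x'^n + H^n)} on the
#' shifted-positive projection \eqn{x' = x - \min(x)}; `kind = "auto"`
#' selects between the two by BIC.
#'
#' @param projection Numeric vector or the tibble from [project_stimulus()]
#'   (burn-in samples are dropped automatically).
#' @param response Matching response values (vector or trace tibble).
#' @param kind `"linear"`, `"hill"` or `"auto"`.
#' @return An object of class `static_nonlinearity`: a list with `kind`,
#'   `coef`, `shift`, `sigma2`, `n`, `bic`, and for `"auto"` both candidate
#'   BICs in `bic_all`.
#' @export
fit_static_nonlinearity <- function(projection, response,
                                    kind = c("auto", "linear", "hill")) {
  kind <- match.arg(kind)
  if (is.data.frame(projection)) {
    keep <- if ("burn_in" %in% names(projection)) !projection$burn_in else TRUE
    x <- projection$value[keep]
  } else {
    x <- projection
    keep <- TRUE
  }
  y <- if (is.data.frame(response)) response$value[keep] else response[keep]
  stopifnot(length(x) == length(y))
  fits <- list()
  if (kind %in% c("linear", "auto")) fits$linear <- fit_snl_linear(x, y)
  if (kind %in% c("hill", "auto")) fits$hill <- fit_snl_hill(x, y)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("static nonlinearity fit failed", call. = FALSE)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(bics)]]
  if (kind == "auto") best$bic_all <- bics
  best
}

fit_snl_linear <- function(x, y) {
  fit <- stats::lm(y ~ x)
  n <- length(y)
  sigma2 <- mean(stats::residuals(fit)^2)
  structure(
    list(
      kind = "linear",
      coef = c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1])),
      shift = 0, sigma2 = sigma2, n = n,
      bic = n * log(max(sigma2, 1e-300)) + 2 * log(n)
    ),
    class = "static_nonlinearity"
  )
}

fit_snl_hill <- function(x, y) {
  shift <- -min(x)
  xp <- x + shift
  span <- max(xp)
  if (span <= 0) {
    return(NULL)
  }
  starts <- expand.grid(
    H = unname(stats::quantile(xp[xp > 0], c(0.25, 0.5, 0.75))),
    n = c(1, 2, 4)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f0 + fmax * xp^nn / (xp^nn + H^nn),
        start = list(
          f0 = min(y), fmax = diff(range(y)),
          H = starts$H[i], nn = starts$n[i]
        ),
        lower = c(f0 = -Inf, fmax = 1e-12, H = span * 1e-4, nn = 0.1),
        upper = c(f0 = Inf, fmax = Inf, H = span * 100, nn = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  cf <- stats::coef(best$fit)
  n <- length(y)
  sigma2 <- best$rss / n
  structure(
    list(
      kind = "hill",
      coef = c(
        f0 = unname(cf["f0"]), f_max = unname(cf["fmax"]),
        H = unname(cf["H"]), n = unname(cf["nn"])
      ),
      shift = shift, sigma2 = sigma2, n = n,
      bic = n * log(max(sigma2, 1e-300)) + 4 * log(n)
    ),
    class = "static_nonlinearity"
  )
}

#' Evaluate a fitted static nonlinearity
#'
#' @param nl A `static_nonlinearity`.
#' @param x Projection values.
#' @return Numeric vector of responses.
#' @export
eval_static_nonlinearity <- function(nl, x) {
  if (nl$kind == "linear") {
    return(nl$coef["a"] * x + nl$coef["b"])
  }
  xp <- pmax(x + nl$shift, 0)
  nl$coef["f0"] + nl$coef["f_max"] * xp^nl$coef["n"] /
    (xp^nl$coef["n"] + nl$coef["H"]^nl$coef["n"])
}

#' Fit the front-end dose-response nonlinearity
#'
#' Hill fit of mean peak response versus odorant concentration; the result is
#' used as the front-end stage of an NLN model (the stimulus is passed
#' through it before the linear filter).
#'
#' @param dose_response A tibble with columns `concentration` (strictly
#'   increasing, >= 3 values) and `peak_response`.
#' @return A `static_nonlinearity` of kind `"hill"` (with `shift = 0`,
#'   domain = concentration). Degenerate (flat) dose-response data are
#'   flagged via `degenerate = TRUE`; gross non-monotonicity via
#'   `nonmonotone = TRUE` (the fit is still returned).
#' @export
fit_front_end_nl <- function(dose_response) {
  assert_columns(dose_response, c("concentration", "peak_response"), "dose_response")
  dr <- dplyr::arrange(dose_response, .data$concentration)
  if (nrow(dr) < 3) stop("need at least 3 concentrations", call. = FALSE)
  x <- dr$concentration
  y <- dr$peak_response
  degenerate <- stats::sd(y) < 1e-12
  nonmono <- !degenerate && stats::cor(x, y, method = "spearman") < 0
  if (nonmono) {
    warning("dose-response is grossly non-monotone; Hill fit may be meaningless")
  }
  if (degenerate) {
    out <- structure(
      list(
        kind = "hill",
        coef = c(f0 = mean(y), f_max = 0, H = stats::median(x), n = 1),
        shift = 0, sigma2 = 0, n = length(y), bic = -Inf
      ),
      class = "static_nonlinearity"
    )
    out$degenerate <- TRUE
    return(out)
  }
  best <- NULL
  for (H0 in unique(stats::quantile(x, c(0.25, 0.5, 0.75)))) {
    for (n0 in c(0.5, 1, 1.5, 2, 3)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ fmax * x^nn / (x^nn + H^nn),
          start = list(fmax = max(y), H = H0, nn = n0),
          lower = c(fmax = 1e-12, H = min(x) * 1e-3, nn = 0.1),
          upper = c(fmax = Inf, H = max(x) * 1e3, nn = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("front-end Hill fit failed to converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  n <- length(y)
  out <- structure(
    list(
      kind = "hill",
      coef = c(
        f0 = 0, f_max = unname(cf["fmax"]), H = unname(cf["H"]),
        n = unname(cf["nn"])
      ),
      shift = 0, sigma2 = best$rss / n, n = n,
      bic = n * log(max(best$rss / n, 1e-300)) + 3 * log(n)
    ),
    class = "static_nonlinearity"
  )
  out$degenerate <- FALSE
  out$nonmonotone <- nonmono
  out
}

#' Fit an LN or NLN encoding model
#'
#' Full estimation pipeline: (optionally) pass the stimulus through a
#' front-end Hill nonlinearity, estimate the linear filter by ridge-regularised
#' reverse correlation on the training segment, project the stimulus, fit the
#' static nonlinearity on the training segment, and evaluate the NR statistic
#' on the held-out final third. The first `discard_s` seconds after stimulus
#' onset (the transient) are excluded from both fitting and evaluation; of
#' the remainder, the first `train_fraction` is used for fitting and the rest
#' for evaluation.
#'
#' @param stimulus A `stimulus_trace`.
#' @param trials Long trace tibble (`time_s`, `value`, optionally `trial_id`);
#'   with >= 2 trials the NR statistic is computed.
#' @param n_lags,ridge_lambda Passed to [estimate_filter()].
#' @param nonlinearity `"auto"`, `"linear"` or `"hill"`.
#' @param front_end Optional `static_nonlinearity` (Hill) making the model
#'   NLN.
#' @param discard_s Transient discarded after onset (default 35 s).
#' @param train_fraction Fraction of the retained record used for fitting
#'   (default 2/3; evaluation uses the final third).
#' @param onset_s Stimulus onset time (default 0).
#' @return An object of class `ln_model` with elements `filter`,
#'   `nonlinearity`, `front_end`, `nr`, `split`.
#' @examples
#' v <- valve_sequence(duration = 60, seed = 2)
#' s <- scale_stimulus(v, 1e-4)
#' tr <- simulate_orn(s, orn_truth(seed = 2))
#' m <- fit_ln(s, tr, discard_s = 10)
#' glance(m)
#' @export
fit_ln <- function(stimulus, trials, n_lags = 80, ridge_lambda = NULL,
                   nonlinearity = "auto", front_end = NULL, discard_s = 35,
                   train_fraction = 2 / 3, onset_s = 0) {
  assert_columns(trials, c("time_s", "value"), "trials")
  if (!"trial_id" %in% names(trials)) trials$trial_id <- 1L
  avg <- average_trials(trials)
  if (nrow(avg) != nrow(stimulus) ||
    max(abs(avg$time_s - stimulus$time_s)) > 1e-9) {
    stop("trials and stimulus must share the time grid", call. = FALSE)
  }
  response <- tibble::tibble(time_s = avg$time_s, value = avg$mean)

  stim_eff <- stimulus
  if (!is.null(front_end)) {
    stim_eff <- tibble::tibble(
      time_s = stimulus$time_s,
      value = eval_static_nonlinearity(front_end, stimulus$value)
    )
  }

  t_keep <- stimulus$time_s >= onset_s + discard_s
  t_kept <- stimulus$time_s[t_keep]
  t_split <- t_kept[1] + train_fraction * (t_kept[length(t_kept)] - t_kept[1])
  train <- t_keep & stimulus$time_s <= t_split
  eval_seg <- t_keep & stimulus$time_s > t_split

  filt <- estimate_filter(stim_eff, response,
    n_lags = n_lags,
    ridge_lambda = ridge_lambda, subset = train
  )
  proj <- project_stimulus(stim_eff, filt)
  fit_rows <- train & !proj$burn_in
  nl <- fit_static_nonlinearity(proj$value[fit_rows], response$value[fit_rows],
    kind = nonlinearity
  )

  model <- structure(
    list(
      filter = filt, nonlinearity = nl, front_end = front_end, nr = NA_real_,
      split = list(
        discard_s = discard_s, train_fraction = train_fraction,
        onset_s = onset_s, eval_from = t_split
      ),
      stimulus = stimulus
    ),
    class = "ln_model"
  )
  if (length(unique(trials$trial_id)) >= 2) {
    pred <- predict(model, stimulus)
    model$nr <- nr_statistic(pred$value[eval_seg],
      trials[trials$time_s %in% stimulus$time_s[eval_seg], ]
    )
  }
  model
}

#' Predict the response of a fitted LN/NLN model
#'
#' @param object An `ln_model`.
#' @param stimulus A `stimulus_trace`; defaults to the one the model was
#'   fitted on.
#' @param ... Unused.
#' @return A tibble `time_s`, `value`.
#' @export
predict.ln_model <- function(object, stimulus = NULL, ...) {
  stimulus <- stimulus %||% object$stimulus
  stim_eff <- stimulus
  if (!is.null(object$front_end)) {
    stim_eff <- tibble::tibble(
      time_s = stimulus$time_s,
      value = eval_static_nonlinearity(object$front_end, stimulus$value)
    )
  }
  proj <- project_stimulus(stim_eff, object$filter)
  tibble::tibble(
    time_s = stimulus$time_s,
    value = as.numeric(eval_static_nonlinearity(object$nonlinearity, proj$value))
  )
}

#' NR goodness-of-fit statistic
#'
#' \eqn{NR = P_R / P_N}: the ratio between the residual power of the model
#' prediction against the trial-mean response,
#' \eqn{P_R = \langle(\bar r - f)^2\rangle_t}, and the noise power across
#' trials, \eqn{P_N = \langle(r_i - \bar r)^2\rangle_{i,t}}. NR < 1 means the
#' prediction lies within the trial-to-trial noise.
#'
#' `evaluate_nr()` applies this to a fitted model on the held-out final
#' segment; `nr_statistic()` is the bare computation on any prediction.
#'
#' @param prediction Numeric vector of model predictions.
#' @param trials Long tibble (`time_s`, `value`, `trial_id`) with >= 2 trials
#'   covering the same samples.
#' @return The NR value (scalar).
#' @export
nr_statistic <- function(prediction, trials) {
  assert_columns(trials, c("time_s", "value", "trial_id"), "trials")
  avg <- average_trials(trials)
  if (length(prediction) != nrow(avg)) {
    stop("prediction and trials must cover the same samples", call. = FALSE)
  }
  n_tr <- avg$n_trials[1]
  if (n_tr < 2) stop("NR needs at least 2 trials", call. = FALSE)
  p_r <- mean((avg$mean - prediction)^2)
  rbar <- avg$mean[match(trials$time_s, avg$time_s)]
  p_n <- mean((trials$value - rbar)^2)
  if (p_n == 0) stop("noise power P_N is zero (identical trials)", call. = FALSE)
  p_r / p_n
}

#' @rdname nr_statistic
#' @param model An `ln_model`.
#' @param stimulus Optional stimulus (defaults to the fitted one).
#' @export
evaluate_nr <- function(model, trials, stimulus = NULL) {
  stopifnot(inherits(model, "ln_model"))
  stimulus <- stimulus %||% model$stimulus
  pred <- predict(model, stimulus)
  keep <- stimulus$time_s > model$split$eval_from &
    stimulus$time_s >= model$split$onset_s + model$split$discard_s
  nr_statistic(
    pred$value[keep],
    trials[trials$time_s %in% stimulus$time_s[keep], ]
  )
}

#' Response gain of a fitted model
#'
#' The slope of the static function: for a linear nonlinearity the
#' coefficient `a`; for a Hill nonlinearity the maximum derivative over the
#' observed projection range.
#'
#' @param model An `ln_model` or a `static_nonlinearity`.
#' @param range Projection range over which to evaluate a Hill derivative;
#'   defaults to `[-shift, -shift + 4H]`.
#' @return Scalar gain.
#' @export
response_gain <- function(model, range = NULL) {
  nl <- if (inherits(model, "ln_model")) model$nonlinearity else model
  if (nl$kind == "linear") {
    return(unname(nl$coef["a"]))
  }
  H <- nl$coef["H"]
  n <- nl$coef["n"]
  fmax <- nl$coef["f_max"]
  range <- range %||% c(-nl$shift, -nl$shift + 4 * H)
  xp <- seq(max(range[1] + nl$shift, 1e-12 * H), range[2] + nl$shift,
    length.out = 512
  )
  deriv <- fmax * n * H^n * xp^(n - 1) / (xp^n + H^n)^2
  max(deriv)
}

#' @export
print.ln_model <- function(x, ...) {
  cat("<ln_model>", if (is.null(x$front_end)) "LN" else "NLN",
    "| filter:", nrow(x$filter), "lags | nonlinearity:", x$nonlinearity$kind,
    "| NR:", format(x$nr, digits = 3), "\n"
  )
  invisible(x)
}

#' Tidy and glance methods for fitted encoding models
#'
#' `tidy()` returns the static-nonlinearity parameters (one row per
#' parameter); `glance()` a one-row model summary (NR, ridge penalty, filter
#' length, nonlinearity kind, model class).
#'
#' @param x,... An `ln_model`; further arguments are ignored.
#' @return A tibble.
#' @method tidy ln_model
#' @export
tidy.ln_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$nonlinearity$coef),
    estimate = unname(x$nonlinearity$coef),
    component = "static_nonlinearity"
  )
}

#' @rdname tidy.ln_model
#' @method glance ln_model
#' @export
glance.ln_model <- function(x, ...) {
  tibble::tibble(
    model = if (is.null(x$front_end)) "LN" else "NLN",
    nr = x$nr,
    nonlinearity = x$nonlinearity$kind,
    n_lags = attr(x$filter, "n_lags"),
    ridge_lambda = attr(x$filter, "ridge_lambda"),
    gain = response_gain(x)
  )
}

#' Serialize an LN model to JSON
#'
#' Stores filter lags and coefficients, nonlinearity and front-end
#' parameters, the NR statistic, the train/test split and a provenance hash.
#'
#' @param model An `ln_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ln_model <- function(model, path) {
  obj <- list(
    model = if (is.null(model$front_end)) "LN" else "NLN",
    filter = list(
      lag_s = model$filter$lag_s, coef = model$filter$coef,
      ridge_lambda = attr(model$filter, "ridge_lambda"),
      n_lags = attr(model$filter, "n_lags")
    ),
    nonlinearity = list(
      kind = model$nonlinearity$kind,
      coef = as.list(model$nonlinearity$coef),
      shift = model$nonlinearity$shift
    ),
    front_end = if (!is.null(model$front_end)) {
      list(
        kind = model$front_end$kind,
        coef = as.list(model$front_end$coef)
      )
    },
    nr = model$nr,
    split = model$split,
    provenance = rlang::hash(model$stimulus)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
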