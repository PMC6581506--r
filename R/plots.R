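#' Plot methods for analysis objects
#'
#' `autoplot()` methods returning ggplot objects: estimated linear filters,
#' fitted encoding models (measured vs predicted response), pulse-peak decay
#' series, and PCA scree/score views. They are convenience views, not
#' figure-reproduction code.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name autoplot-olfadapt
NULL

#' @rdname autoplot-olfadapt
#' @method autoplot linear_filter
#' @export
autoplot.linear_filter <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$coef)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "filter coefficient (unit norm)")
}

#' @rdname autoplot-olfadapt
#' @param trials Optional trial tibble to overlay the measured mean response.
#' @method autoplot ln_model
#' @export
autoplot.ln_model <- function(object, trials = NULL, ...) {
  pred <- predict(object)
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "response", title = sprintf(
      "%s model, NR = %.3g",
      if (is.null(object$front_end)) "LN" else "NLN", object$nr
    ))
  if (!is.null(trials)) {
    avg <- average_trials(trials)
    p <- p + ggplot2::geom_line(
      data = avg, ggplot2::aes(x = .data$time_s, y = .data$mean),
      colour = "black", alpha = 0.6
    )
  }
  p
}

#' @rdname autoplot-olfadapt
#' @method autoplot pulse_peaks
#' @export
autoplot.pulse_peaks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$onset_s, y = .data$peak)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pulse onset (s)", y = "peak response")
}

#' @rdname autoplot-olfadapt
#' @method autoplot population_pca
#' @export
autoplot.population_pca <- function(object, ...) {
  df <- tidy.population_pca(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$component),
    y = .data$explained_variance_fraction
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component", y = "explained variance fraction")
}

#' Per-concentration CV against the expected CV
#'
#' @param cv A [compute_cv()] report.
#' @param expected Optional scalar from [expected_cv()], drawn as a
#'   horizontal reference.
#' @return A `ggplot`.
#' @export
plot_cv_report <- function(cv, expected = NULL) {
  p <- ggplot2::ggplot(cv, ggplot2::aes(
    x = log10(.data$concentration),
    y = .data$cv
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 concentration", y = "CV of PC1 scores")
  if (!is.null(expected)) {
    p <- p + ggplot2::geom_hline(
      yintercept = as.numeric(expected),
      linetype = 2, colour = "grey40"
    )
  }
  p
}
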