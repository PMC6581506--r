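#' Parametric temporal-filter specification
#'
#' The three exponential families used to describe linear filters:
#' `k1`: \eqn{A_1 e^{-t/\tau_1}}; `k2`: \eqn{A_1 e^{-t/\tau_1} + A_2}
#' (exponential plus constant); `k3`: \eqn{A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}}
#' (double exponential, biphasic when \eqn{A_2 < 0}).
#'
#' @param family One of `"k1"`, `"k2"`, `"k3"`.
#' @param A1,tau1 Amplitude and timescale (s) of the first exponential.
#' @param A2 Second amplitude (constant for `k2`, exponential for `k3`).
#' @param tau2 Second timescale (s), `k3` only.
#' @return An object of class `filter_spec`.
#' @examples
#' eval_filter(filter_spec("k1", A1 = 1, tau1 = 0.5), lags = seq(0, 2, 0.05))
#' @export
filter_spec <- function(family = c("k1", "k2", "k3"), A1, tau1,
                        A2 = NULL, tau2 = NULL) {
  family <- match.arg(family)
  if (tau1 <= 0) stop("tau1 must be positive", call. = FALSE)
  if (family != "k1" && is.null(A2)) {
    stop(sprintf("family %s needs A2", family), call. = FALSE)
  }
  if (family == "k3") {
    if (is.null(tau2) || tau2 <= 0) stop("k3 needs tau2 > 0", call. = FALSE)
  }
  structure(
    list(family = family, A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2),
    class = "filter_spec"
  )
}

#' @rdname filter_spec
#' @param spec A `filter_spec`.
#' @param lags Non-negative lag times (s) at which to evaluate the filter.
#' @export
eval_filter <- function(spec, lags) {
  stopifnot(inherits(spec, "filter_spec"), all(lags >= 0))
  switch(spec$family,
    k1 = spec$A1 * exp(-lags / spec$tau1),
    k2 = spec$A1 * exp(-lags / spec$tau1) + spec$A2,
    k3 = spec$A1 * exp(-lags / spec$tau1) + spec$A2 * exp(-lags / spec$tau2)
  )
}

# TRUE for filter shapes without a sign change (k1 always; k2/k3 depending on
# amplitudes).
is_monophasic <- function(spec, horizon = 4, dt = 0.05) {
  k <- eval_filter(spec, seq(0, horizon, by = dt))
  all(k >= -1e-12) || all(k <= 1e-12)
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>", x$family, " A1=", x$A1, " tau1=", x$tau1,
    if (!is.null(x$A2)) paste0(" A2=", x$A2),
    if (!is.null(x$tau2)) paste0(" tau2=", x$tau2), "\n",
    sep = ""
  )
  invisible(x)
}
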