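# Internal numerical helpers shared across modules.

# Exact discretisation of the first-order low-pass tau*y' + y = x assuming the
# input is piecewise linear between samples (first-order hold). The kernel is
# the unit-area causal exponential (1/tau) exp(-t/tau), so a constant input is
# reproduced exactly at steady state. `exp_deconv()` inverts this recursion
# algebraically sample-by-sample, which makes convolve -> deconvolve an
# identity to machine precision.
exp_conv <- function(x, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  a <- exp(-dt / tau)
  r <- tau / dt
  c2 <- 1 - r * (1 - a)
  c1 <- r * (1 - a) - a
  n <- length(x)
  y <- numeric(n)
  y[1] <- x[1] # system assumed at steady state with x[1] before the record
  if (n > 1) {
    for (i in 2:n) y[i] <- a * y[i - 1] + c1 * x[i - 1] + c2 * x[i]
  }
  y
}

exp_deconv <- function(y, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  a <- exp(-dt / tau)
  r <- tau / dt
  c2 <- 1 - r * (1 - a)
  c1 <- r * (1 - a) - a
  n <- length(y)
  x <- numeric(n)
  x[1] <- y[1]
  if (n > 1) {
    for (i in 2:n) x[i] <- (y[i] - a * y[i - 1] - c1 * x[i - 1]) / c2
  }
  x
}

# Causal discrete convolution (integral approximation): y[t] = sum_j k[j] x[t-j] dt,
# with x treated as zero before the record starts.
causal_conv <- function(x, k, dt) {
  n <- length(x)
  y <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  y * dt
}

# Gaussian smoothing with a truncated (4 sd), renormalised kernel; edges are
# padded by replication so that flat signals stay flat.
gaussian_smooth <- function(x, sd_s, dt) {
  if (sd_s <= 0) {
    return(x)
  }
  half <- max(1L, ceiling(4 * sd_s / dt))
  g <- stats::dnorm(seq(-half, half) * dt, sd = sd_s)
  g <- g / sum(g)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::convolve(xp, rev(g), type = "open")
  y[(2 * half + 1):(2 * half + length(x))]
}

# Sample interval of a uniform time grid, with a tolerance check.
grid_dt <- function(time_s, tol = 1e-6) {
  d <- diff(time_s)
  if (length(d) == 0) {
    stop("time grid needs at least two samples", call. = FALSE)
  }
  if (max(abs(d - d[1])) > tol * max(d[1], 1)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  d[1]
}

# Evaluate a possibly-seeded expression without disturbing the caller's RNG
# stream when no seed is supplied.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
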