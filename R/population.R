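#' Build a glomerulus-by-sample population matrix
#'
#' Assembles per-glomerulus mean responses into a matrix whose rows are
#' glomeruli and whose columns are retained samples concatenated across
#' concentrations: either all steady-state time points (`mode =
#' "timepoints"`, the initial transient discarded) or per-pulse peak
#' responses (`mode = "pulse_peaks"`).
#'
#' @param data Long tibble with columns `glomerulus`, `concentration`,
#'   `time_s`, `value` (e.g. from [simulate_population()]).
#' @param mode `"timepoints"` or `"pulse_peaks"`.
#' @param discard_initial Leading seconds discarded from each concentration
#'   block; defaults to 35 for `"timepoints"` and 0 for `"pulse_peaks"`.
#' @param valve Required in `"pulse_peaks"` mode: the shared
#'   [valve_sequence()].
#' @param latency Peak-search latency, seconds (pulse mode).
#' @return An object of class `population_matrix`: list with `values` (the
#'   matrix), `samples` (per-column metadata tibble) and `mode`.
#' @export
build_population_matrix <- function(data, mode = c("timepoints", "pulse_peaks"),
                                    discard_initial = NULL, valve = NULL,
                                    latency = 0.3) {
  mode <- match.arg(mode)
  assert_columns(data, c("glomerulus", "concentration", "time_s", "value"), "data")
  discard_initial <- discard_initial %||% if (mode == "timepoints") 35 else 0
  gloms <- unique(data$glomerulus)
  concs <- sort(unique(data$concentration))
  blocks <- list()
  meta <- list()
  for (conc in concs) {
    d <- data[data$concentration == conc, ]
    counts <- table(d$glomerulus)
    if (length(counts) != length(gloms)) {
      stop(sprintf("missing glomerulus at concentration %g", conc), call. = FALSE)
    }
    if (length(unique(counts)) != 1) {
      stop("time grids differ between glomeruli", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(d[c("glomerulus", "time_s", "value")],
      names_from = "glomerulus", values_from = "value"
    )
    wide <- dplyr::arrange(wide, .data$time_s)
    if (anyNA(wide)) stop("time grids differ between glomeruli", call. = FALSE)
    if (mode == "timepoints") {
      keep <- wide$time_s >= discard_initial
      blocks[[length(blocks) + 1]] <- t(as.matrix(wide[keep, gloms]))
      meta[[length(meta) + 1]] <- tibble::tibble(
        concentration = conc, sample = wide$time_s[keep]
      )
    } else {
      if (is.null(valve)) stop("pulse_peaks mode needs the valve", call. = FALSE)
      pk <- purrr::map(gloms, function(g) {
        tr <- tibble::tibble(
          time_s = wide$time_s,
          value = wide[[g]]
        )
        extract_pulse_peaks(tr, valve, latency = latency)
      })
      onsets <- pk[[1]]$onset_s
      keep <- onsets >= discard_initial
      blocks[[length(blocks) + 1]] <-
        do.call(rbind, purrr::map(pk, function(p) p$peak[keep]))
      meta[[length(meta) + 1]] <- tibble::tibble(
        concentration = conc, sample = onsets[keep]
      )
    }
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- gloms
  structure(
    list(values = values, samples = dplyr::bind_rows(meta), mode = mode),
    class = "population_matrix"
  )
}

#' Principal component analysis in glomerular space
#'
#' Standard PCA with observations = samples (time points or pulses) and
#' variables = glomeruli. By default the data are centered on per-glomerulus
#' means; `center = FALSE` analyses raw response space (variance about the
#' origin), which is the relevant space for the unidimensionality of
#' combinatorial representations under receptor recruitment. Component signs
#' are fixed deterministically (largest-magnitude loading positive), and PC1
#' is additionally flipped if its mean score is negative so that CVs of PC1
#' scores are well defined.
#'
#' @param pop A [build_population_matrix()] result.
#' @param n_components Number of components to keep (default: all).
#' @param center Center per-glomerulus means (default `TRUE`).
#' @return An object of class `population_pca`: list with `loadings`
#'   (glomeruli x components), `scores` (tibble: sample metadata + `PC1`,
#'   ...), `explained_variance_fraction`, `center`.
#' @export
run_pca <- function(pop, n_components = NULL, center = TRUE) {
  stopifnot(inherits(pop, "population_matrix"))
  X <- t(pop$values) # samples x glomeruli
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  n_components <- n_components %||% min(dim(X))
  if (n_components > min(dim(X))) {
    stop("more components requested than available", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = center, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    flip <- rot[which.max(abs(rot[, j])), j] < 0
    if (j == 1 && mean(scores[, 1]) < 0) flip <- TRUE
    if (flip) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  keep <- seq_len(n_components)
  sc <- tibble::as_tibble(scores[, keep, drop = FALSE])
  structure(
    list(
      loadings = rot[, keep, drop = FALSE],
      scores = dplyr::bind_cols(pop$samples, sc),
      explained_variance_fraction = frac[keep],
      center = center
    ),
    class = "population_pca"
  )
}

#' Linear rescaling of the combinatorial representation
#'
#' Quantifies the multiplicative ORN-to-PN rescaling over time: linear fits
#' of PN PC1 scores against ORN PC1 scores over an initial and a final pulse
#' window. The ratio `slope_final / slope_initial` estimates the common
#' multiplicative gain change (equal to \eqn{1 - d} for a population with a
#' shared degree of slow adaptation).
#'
#' @param orn_scores,pn_scores Numeric vectors of per-pulse PC1 scores with
#'   matched pulse indexing.
#' @param first_window,last_window Integer vectors of pulse indices for the
#'   initial and final fits; they must not overlap.
#' @return A tibble with `slope_initial`, `slope_final` and `ratio`.
#' @export
scaling_fit <- function(orn_scores, pn_scores,
                        first_window = seq_len(5),
                        last_window = NULL) {
  if (length(orn_scores) != length(pn_scores)) {
    stop("score series must have matched pulse indexing", call. = FALSE)
  }
  n <- length(orn_scores)
  last_window <- last_window %||% seq(n - 4, n)
  if (max(first_window) > n || max(last_window) > n ||
    min(first_window) < 1 || min(last_window) < 1) {
    stop("windows exceed the pulse count", call. = FALSE)
  }
  if (length(intersect(first_window, last_window)) > 0) {
    stop("windows overlap", call. = FALSE)
  }
  s1 <- unname(stats::coef(stats::lm(pn_scores[first_window] ~ orn_scores[first_window]))[2])
  s2 <- unname(stats::coef(stats::lm(pn_scores[last_window] ~ orn_scores[last_window]))[2])
  tibble::tibble(slope_initial = s1, slope_final = s2, ratio = s2 / s1)
}

#' Coefficient of variation of PC1 scores per concentration
#'
#' \eqn{CV = \sigma/m} of the stimulus representation along the first
#' principal component, per concentration.
#'
#' @param scores A tibble with columns `concentration` and `PC1` (e.g.
#'   `run_pca(...)$scores`).
#' @return A tibble of class `cv_report` with `concentration`, `m`, `sigma`,
#'   `cv`.
#' @export
compute_cv <- function(scores) {
  assert_columns(scores, c("concentration", "PC1"), "scores")
  out <- dplyr::summarise(
    dplyr::group_by(scores, .data$concentration),
    m = mean(.data$PC1), sigma = stats::sd(.data$PC1), .groups = "drop"
  )
  if (any(out$m <= 0)) {
    stop("mean PC1 score must be positive (check the sign convention)",
      call. = FALSE
    )
  }
  out$cv <- out$sigma / out$m
  structure(out, class = c("cv_report", class(out)))
}

#' Expected CV of a filtered binary stimulus
#'
#' The CV of the valve sequence after causal convolution with a unit-area
#' exponential filter of timescale `tau_integration` (default 0.54 s, the
#' mean integration time across glomeruli and concentrations). A burn-in of
#' `5 * tau_integration` is discarded. This is the model prediction for the
#' CV of a neural representation that integrates the stimulus with that
#' timescale.
#'
#' @param valve A [valve_sequence()], or a list of them (the mean expected CV
#'   across realizations is returned together with per-seed values).
#' @param tau_integration Integration timescale in seconds.
#' @return For a single valve, a scalar. For a list, a scalar mean with the
#'   per-realization values as attribute `per_seed`.
#' @export
expected_cv <- function(valve, tau_integration = 0.54) {
  if (tau_integration <= 0) stop("tau_integration must be positive", call. = FALSE)
  if (is.data.frame(valve)) valve <- list(valve)
  vals <- purrr::map_dbl(valve, function(v) {
    assert_columns(v, c("time_s", "state"), "valve")
    dt <- grid_dt(v$time_s)
    if (nrow(v) * dt < 10 * tau_integration) {
      stop("record must be at least 10 integration timescales long", call. = FALSE)
    }
    y <- exp_conv(v$state, tau_integration, dt)
    burn <- ceiling(5 * tau_integration / dt)
    y <- y[-seq_len(burn)]
    stats::sd(y) / mean(y)
  })
  out <- mean(vals)
  if (length(vals) > 1) attr(out, "per_seed") <- vals
  out
}

#' @export
print.population_pca <- function(x, ...) {
  cat(
    "<population_pca>", ncol(x$loadings), "components;",
    "PC1 explains", sprintf("%.1f%%", 100 * x$explained_variance_fraction[1]),
    if (x$center) "(centered)" else "(raw)", "\n"
  )
  invisible(x)
}

#' Tidy method for population PCA
#'
#' @param x,... A `population_pca`.
#' @return A tibble with one row per component: explained variance fraction
#'   and cumulative fraction.
#' @method tidy population_pca
#' @export
tidy.population_pca <- function(x, ...) {
  frac <- x$explained_variance_fraction
  tibble::tibble(
    component = seq_along(frac),
    explained_variance_fraction = frac,
    cumulative = cumsum(frac)
  )
}
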