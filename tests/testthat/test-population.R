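test_that("population matrices assemble glomeruli by retained samples", {
  v <- quick_valve(duration = 30, seed = 3)
  concs <- 10^c(-4.3, -4)
  stimuli <- lapply(concs, function(C) scale_stimulus(v, C))
  specs <- population_specs(seed = 3, noise_frac = 0)
  pop <- simulate_population(stimuli, specs, "ORN")

  m <- build_population_matrix(pop, "timepoints", discard_initial = 10)
  expect_identical(nrow(m$values), 5L)
  expect_identical(ncol(m$values), nrow(m$samples))
  expect_true(all(m$samples$sample >= 10))
  # noiseless simulation: matrix equals the generator output exactly
  one <- pop[pop$glomerulus == "g2" & pop$concentration == concs[1] &
    pop$time_s >= 10, ]
  expect_equal(unname(m$values["g2", m$samples$concentration == concs[1]]),
    one$value,
    tolerance = 1e-12
  )

  # single glomerulus, single concentration: a 1 x T matrix equal to the trace
  solo <- pop[pop$glomerulus == "g1" & pop$concentration == concs[1], ]
  m1 <- build_population_matrix(solo, "timepoints", discard_initial = 0)
  expect_identical(dim(m1$values), c(1L, nrow(solo)))
  expect_equal(unname(m1$values[1, ]), solo$value)
  expect_identical(qr(m1$values)$rank, 1L)

  # pulse-peak mode: one column per open run per concentration
  mp <- build_population_matrix(pop, "pulse_peaks", valve = v, discard_initial = 0)
  n_open <- sum(rle(v$state)$values == 1)
  expect_identical(ncol(mp$values), n_open * length(concs))

  expect_error(
    build_population_matrix(pop[pop$glomerulus != "g1" | pop$concentration != concs[1], ]),
    "missing glomerulus"
  )
})

test_that("PCA has exact behaviour on constructed matrices", {
  # rank-1 matrix: PC1 explains everything
  u <- c(1, 2, 3, 4, 5)
  w <- sin(seq(0, 6, length.out = 40)) + 2
  pop <- structure(
    list(
      values = outer(u, w),
      samples = tibble::tibble(concentration = 1, sample = seq_along(w)),
      mode = "timepoints"
    ),
    class = "population_matrix"
  )
  p <- run_pca(pop, center = FALSE)
  expect_equal(p$explained_variance_fraction[1], 1, tolerance = 1e-12)

  # two orthogonal patterns with variance ratio 4:1 -> fractions 0.8 / 0.2
  set.seed(1)
  n <- 20000
  a <- rep(c(1, -1), n / 2) * 2 # sd 2 along (1,0)
  b <- rep(c(1, 1, -1, -1), n / 4) * 1 # sd 1 along (0,1)
  X <- cbind(a, b)
  pop2 <- structure(
    list(
      values = t(X),
      samples = tibble::tibble(concentration = 1, sample = seq_len(n)),
      mode = "timepoints"
    ),
    class = "population_matrix"
  )
  p2 <- run_pca(pop2, center = TRUE)
  expect_equal(p2$explained_variance_fraction, c(0.8, 0.2), tolerance = 1e-6)

  # permuting glomeruli permutes loadings, leaves explained fractions alone
  perm <- c(2, 1)
  pop3 <- pop2
  pop3$values <- pop2$values[perm, ]
  p3 <- run_pca(pop3, center = TRUE)
  expect_equal(p3$explained_variance_fraction, p2$explained_variance_fraction)
  expect_equal(abs(p3$loadings[perm, 1]), abs(p2$loadings[, 1]), ignore_attr = TRUE)
})

test_that("PCA reconstruction from all components is exact", {
  set.seed(4)
  X <- matrix(rnorm(5 * 200), nrow = 5) + 2
  pop <- structure(
    list(
      values = X,
      samples = tibble::tibble(concentration = 1, sample = 1:200),
      mode = "timepoints"
    ),
    class = "population_matrix"
  )
  p <- run_pca(pop, center = TRUE)
  centered <- t(X) - matrix(rowMeans(X), 200, 5, byrow = TRUE)
  scores <- as.matrix(p$scores[paste0("PC", 1:5)])
  recon <- scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centered)), 1e-10)
})

test_that("PC1 is time-invariant under pure shared multiplicative decay", {
  v <- quick_valve(duration = 60, seed = 6)
  stimuli <- lapply(10^c(-4.3, -4), function(C) scale_stimulus(v, C))
  specs <- population_specs(d = 0.6, tau_slow = 8, seed = 6, noise_frac = 0)
  pn <- simulate_population(stimuli, specs, "PN")
  m <- build_population_matrix(pn, "timepoints", discard_initial = 0)
  early <- m$values[, m$samples$sample < 15 & m$samples$concentration == 10^-4]
  late <- m$values[, m$samples$sample > 45 & m$samples$concentration == 10^-4]
  pc1 <- function(X) {
    v1 <- svd(X)$u[, 1]
    v1 * sign(v1[which.max(abs(v1))])
  }
  cosine <- sum(pc1(early) * pc1(late))
  expect_gt(cosine, 0.999)
})

test_that("window slope fits quantify a constructed rescaling", {
  set.seed(5)
  orn <- runif(40, 0.5, 2)
  pn <- 2 * orn
  sf <- scaling_fit(orn, pn, first_window = 1:10, last_window = 31:40)
  expect_equal(sf$slope_initial, 2, tolerance = 1e-9)
  expect_equal(sf$slope_final, 2, tolerance = 1e-9)
  expect_equal(sf$ratio, 1, tolerance = 1e-9)

  pn2 <- pn
  pn2[31:40] <- 0.4 * pn[31:40]
  sf2 <- scaling_fit(orn, pn2, first_window = 1:10, last_window = 31:40)
  expect_equal(sf2$ratio, 0.4, tolerance = 1e-9)

  expect_error(scaling_fit(orn, pn, first_window = 1:10, last_window = 5:20), "overlap")
  expect_error(scaling_fit(orn, pn, first_window = 1:10, last_window = 39:41), "exceed")
})

test_that("stationary generators give overlapping first and last pulse clouds", {
  v <- valve_sequence(duration = 120, seed = 10)
  stimuli <- lapply(10^c(-4.3, -4, -3.7), function(C) scale_stimulus(v, C))
  specs <- population_specs(seed = 10)
  orn <- simulate_population(stimuli, specs, "ORN") # d forced to 0
  m <- build_population_matrix(orn, "pulse_peaks", valve = v, discard_initial = 0)
  p <- run_pca(m, center = FALSE)
  sc <- dplyr::mutate(dplyr::group_by(p$scores, .data$concentration),
    pulse = dplyr::row_number()
  )
  n <- max(sc$pulse)
  first <- sc$PC1[sc$pulse <= 8]
  last <- sc$PC1[sc$pulse > n - 8]
  # same-stimulus ORN representation is stable: last-vs-first mean ratio near 1
  expect_equal(mean(last) / mean(first), 1, tolerance = 0.25)
})

test_that("CV reports follow the definition and its invariances", {
  sc <- tibble::tibble(
    concentration = rep(c(1e-4, 1e-3), each = 4),
    PC1 = c(rep(1, 4), c(0, 2, 0, 2) * 3)
  )
  cv <- compute_cv(sc)
  expect_equal(cv$cv[cv$concentration == 1e-4], 0)
  expect_equal(cv$cv[cv$concentration == 1e-3], sd(c(0, 2, 0, 2)) / 1, tolerance = 1e-12)

  sc2 <- dplyr::mutate(sc, PC1 = 7 * .data$PC1)
  expect_equal(compute_cv(sc2)$cv, cv$cv)

  expect_error(
    compute_cv(tibble::tibble(concentration = 1, PC1 = c(-1, -2))),
    "positive"
  )
})

test_that("saturation compresses response fluctuations (CV drops)", {
  v <- valve_sequence(duration = 120, seed = 12)
  stimuli <- lapply(10^c(-4.3, -2.5), function(C) scale_stimulus(v, C))
  specs <- population_specs(seed = 12)
  orn <- simulate_population(stimuli, specs, "ORN")
  m <- build_population_matrix(orn, "timepoints", discard_initial = 35)
  p <- run_pca(m, center = FALSE)
  cv <- compute_cv(p$scores)
  cv_mid <- cv$cv[cv$concentration == 10^-4.3]
  cv_sat <- cv$cv[cv$concentration == 10^-2.5]
  expect_lt(cv_sat, cv_mid)
})

test_that("the expected CV of the filtered stimulus matches closed-form limits", {
  v <- valve_sequence(
    duration = 240, dt_update = 0.3, max_run = Inf,
    open_probability = 0.5, seed = 20
  )
  stim_cv <- sd(v$state) / mean(v$state)

  # delta-filter limit: expected CV tends to the stimulus CV
  expect_equal(expected_cv(v, tau_integration = 1e-3), stim_cv, tolerance = 0.01)

  # strong averaging: expected CV collapses toward zero
  expect_lt(expected_cv(v, tau_integration = 20), 0.2 * stim_cv)

  # monotone non-increasing in the integration timescale
  taus <- c(0.05, 0.2, 0.54, 1, 3, 8)
  cvs <- vapply(taus, function(tau) expected_cv(v, tau), numeric(1))
  expect_true(all(diff(cvs) < 0))

  expect_error(
    expected_cv(valve_sequence(duration = 3, seed = 1), tau_integration = 1),
    "10 integration"
  )
})

test_that("the CV attenuation at tau 0.54 matches the closed-form kernel integral", {
  # oracle: output variance of an exponential filter driven by a process with
  # triangular autocovariance C(s) = sigma2 (1 - |s|/b), via direct quadrature
  b <- 0.3
  tau <- 0.54
  du <- 0.001
  u <- seq(0, 10, by = du)
  kern <- exp(-u / tau) / tau
  # var_out = int int k(u) k(w) C(u - w) du dw, C normalized to sigma2 = 1
  Cfun <- function(s) pmax(0, 1 - abs(s) / b)
  var_out <- 0
  for (shift in seq(-b, b, by = du)) {
    idx <- round(abs(shift) / du)
    overlap <- sum(kern[1:(length(kern) - idx)] * kern[(1 + idx):length(kern)]) * du
    var_out <- var_out + Cfun(shift) * overlap * du
  }
  ratio_expected <- sqrt(var_out) # CV ratio: mean is preserved by unit area

  ratios <- vapply(1:12, function(s) {
    v <- valve_sequence(
      duration = 240, dt_update = 0.3, max_run = Inf,
      open_probability = 0.5, seed = s
    )
    expected_cv(v, tau) / (sd(v$state) / mean(v$state))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - ratio_expected), 0.02)
  expect_lt(abs(mean(ratios) - 0.48), 0.02)
})
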