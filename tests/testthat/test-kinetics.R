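test_that("truncated-exponential MLE recovers the rate (grid-search oracle)", {
  set.seed(1)
  k_true <- 0.02; t0 <- 15; tf <- 135
  t <- rexp(30000, k_true)
  t <- t[t >= t0 & t <= tf][1:5000]
  fit <- fit_binding_rate(t, acquisition_window(t0, tf))
  expect_lt(abs(fit$k - k_true), 3 * fit$se)
  expect_true(fit$depletion_detected)

  # oracle: brute-force grid maximization of the truncated log-likelihood
  grid <- seq(0.001, 0.1, by = 1e-5)
  ll <- sapply(grid, function(k) {
    length(t) * log(k) - k * sum(t) -
      length(t) * log(exp(-k * t0) - exp(-k * tf))
  })
  expect_lt(abs(fit$k - grid[which.max(ll)]), 2e-5 + fit$k * 1e-3)
})

test_that("uniform arrival times are flagged as no detectable depletion", {
  set.seed(2)
  t <- runif(2000, 15, 135)
  fit <- fit_binding_rate(t, acquisition_window(15, 135))
  expect_false(fit$depletion_detected)
  expect_lt(fit$k * 120, 0.5)  # k -> 0 limit
})

test_that("rate fit preconditions and the binned alternative", {
  expect_error(fit_binding_rate(runif(20, 15, 135)), "at least 50")
  expect_error(fit_binding_rate(rep(20, 100)), "equal")
  expect_error(fit_binding_rate(c(runif(99, 15, 135), 500)), "within")

  set.seed(3)
  t <- rexp(50000, 0.02)
  t <- t[t >= 15 & t <= 135][1:5000]
  fb <- fit_binding_rate(t, method = "binned")
  expect_lt(abs(fb$k - 0.02) / 0.02, 0.15)
})

test_that("mean length: weighted and literal conventions", {
  expect_equal(as.numeric(mean_length(c(100, 300), c(1, 1))), 200)
  expect_equal(as.numeric(mean_length(c(100, 300), c(3, 1))), 150)
  lit <- mean_length(c(100, 300), c(0.75, 0.25), mode = "literal")
  expect_equal(as.numeric(lit), 75)  # weighted / N with fractional abundances
  expect_equal(attr(lit, "mode"), "literal")
  expect_error(mean_length(c(100, 300), c(0, 0)), "not all")
  expect_error(mean_length(c(100, 300), c(1)), "equal length")
})

test_that("scaling factor and per-species rates follow the power law", {
  expect_equal(scaling_alpha(0.02, 200), 0.02 * 200^0.72, tolerance = 1e-12)
  expect_equal(scaling_alpha(0.02, 200), 0.907343, tolerance = 1e-5)
  expect_equal(scaling_alpha(0.05, 1, beta = -0.72), 0.05)
  expect_equal(scaling_alpha(0.05, 200, beta = 0), 0.05)
  expect_error(scaling_alpha(-1, 200), "> 0")

  expect_equal(species_rate(1, 1), 1)
  expect_equal(species_rate(0.5, 100), 0.018154, tolerance = 1e-5)
  # doubling the length multiplies the rate by 2^-0.72
  expect_equal(species_rate(0.5, 800) / species_rate(0.5, 400), 2^-0.72,
               tolerance = 1e-12)
  expect_error(species_rate(0.5, 0), ">= 1")
})

test_that("diffusion correction matches the fraction-observed oracle", {
  win <- acquisition_window(15, 135)
  # derived values: a' = a e^(k t0) / (1 - e^(-k (tf - t0)))
  expect_equal(diffusion_correction(100, 0.01, win), 166.26, tolerance = 1e-4)
  expect_equal(diffusion_correction(100, 0.05, win), 212.2261, tolerance = 1e-4)

  # full-observation limit: t0 = 0, tf -> infinity
  expect_equal(diffusion_correction(100, 0.01, acquisition_window(0, 1e9)),
               100, tolerance = 1e-6)

  # oracle: the in-window fraction of an exponential lifetime is the
  # numerical integral of k e^-kt over the window, and the correction
  # factor must be its reciprocal (a' restores the full population)
  for (k in 10^seq(-4, 0, length.out = 30)) {
    frac <- integrate(function(t) k * exp(-k * t), win$t0, win$t_final,
                      rel.tol = 1e-13)$value
    expect_equal(diffusion_correction(1, k, win), 1 / frac, tolerance = 1e-9)
  }
  expect_error(diffusion_correction(1, 0, win), "> 0")
  expect_error(diffusion_correction(-1, 0.01, win), ">= 0")
})

test_that("correction factor is always >= 1", {
  win <- acquisition_window(15, 135)
  for (k in 10^seq(-4, 0, length.out = 50)) {
    expect_gte(diffusion_correction(1, k, win), 1)
  }
  expect_gte(diffusion_correction(1, 0.5, acquisition_window(0, 10)), 1)
})

test_that("longer movies weaken the correction toward e^(k t0)", {
  k <- 0.01; t0 <- 15
  tfs <- c(60, 135, 300, 1000, 1e5)
  f <- sapply(tfs, function(tf) diffusion_correction(1, k, acquisition_window(t0, tf)))
  expect_true(all(diff(f) < 0))
  expect_equal(f[length(f)], exp(k * t0), tolerance = 1e-6)
})

test_that("mole fractions renormalize and validate", {
  expect_equal(mole_fractions(rep(2, 6)), rep(1 / 6, 6))
  expect_equal(mole_fractions(c(3, 1)), c(0.75, 0.25))
  set.seed(4)
  x <- runif(8)
  expect_lt(abs(sum(mole_fractions(x)) - 1), 1e-9)
  expect_error(mole_fractions(c(0, 0)), "> 0")
  expect_error(mole_fractions(numeric()), "at least one")
})

test_that("round trip: depletion bias is removed on an equimolar ladder", {
  mix <- equimolar_mixture(c(200L, 400L, 800L, 1200L), n_molecules = 6000L)
  ev <- simulate_event_stream(mix, kinetics = kinetics_model(alpha = 0.2),
                              seed = 9)
  pk <- fit_gaussian_mixture(ev$contrast, init = 4, bin_width = 1e-4)
  pk <- peaks_with_lengths(pk, c(200, 400, 800, 1200))
  raw_frac <- pk$area / sum(pk$area)
  expect_true(all(diff(raw_frac) < 0))  # uncorrected: strictly decreasing

  ab <- correct_abundances(pk, ev$time_s, acquisition_window(15, 135))
  ab <- abundance_se(ab, bin_width = 1e-4)
  expect_true(all(abs(ab$mole_fraction - 0.25) < 3 * ab$mole_fraction_se))
  expect_true(all(ab$corrected_area >= ab$raw_area))
  expect_lt(abs(sum(ab$mole_fraction) - 1), 1e-9)
})

test_that("kinetics invariants: alpha consistency and glance output", {
  mix <- equimolar_mixture(c(200L, 400L, 800L), n_molecules = 8000L)
  ev <- simulate_event_stream(mix, seed = 10)
  pk <- fit_gaussian_mixture(ev$contrast, init = 3, bin_width = 1e-4)
  pk <- peaks_with_lengths(pk, c(200, 400, 800))
  ab <- correct_abundances(pk, ev$time_s)
  kin <- attr(ab, "kinetics")
  expect_lt(abs(kin$alpha - kin$k / kin$mean_length^kin$beta) / kin$alpha, 1e-9)
  gl <- glance(ab)
  expect_equal(gl$n_species, 3)
  expect_equal(gl$alpha, kin$alpha)
})
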