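test_that("band-summed counts match an explicit loop over photosite wavelengths", {
  wmap <- wavelength_map(c(320, 2))
  ones <- rep(1, 288)
  n_in_band <- sum(vapply(seq_len(288), function(p)
    wmap$lambda[p] >= 380 && wmap$lambda[p] <= 780, logical(1)))
  expect_equal(summed_band_counts(ones, wmap), n_in_band)

  set.seed(11)
  c_p <- stats::rnorm(288)
  oracle <- 0
  for (p in seq_len(288)) {
    if (wmap$lambda[p] >= 380 && wmap$lambda[p] <= 780) oracle <- oracle + c_p[p]
  }
  expect_equal(summed_band_counts(c_p, wmap), oracle)
  expect_error(summed_band_counts(c_p, wmap, 0, 100), "no photosites")
})

test_that("expected rates are proportional to exposure and scaled to max one", {
  expect_equal(expected_rates(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(expected_rates(7), 1)
  octaves <- expected_rates(2^(0:10))
  expect_equal(octaves[11], 1)
  expect_equal(octaves[-1] / octaves[-11], rep(2, 10))
  expect_error(expected_rates(numeric(0)), "empty")
})

test_that("the linearisation fit recovers generating coefficients from a noiseless ramp", {
  truth <- unit_c_model()
  fit <- fit_linearisation(oracle_ramp(truth))
  expect_lt(abs(fit$a - 0.14231), 1e-3)
  expect_lt(abs(fit$b - 1.06125), 1e-3)
  expect_gt(fit$r_squared, 0.99999)
})

test_that("a perfectly linear ramp fits as the identity response", {
  t_ms <- 2^(0:10)
  ramp <- data.frame(integration_ms = t_ms, summed_counts = 7 * t_ms,
                     saturated = FALSE)
  fit <- fit_linearisation(ramp)
  expect_gte(fit$r_squared, 0.999)
  x <- seq(0.05, 1, by = 0.05)
  expect_equal(lin_apply(x, fit), x, tolerance = 1e-6)
})

test_that("the fit is invariant to the overall scale of the summed counts", {
  ramp <- oracle_ramp(unit_c_model())
  fit1 <- fit_linearisation(ramp)
  ramp$summed_counts <- ramp$summed_counts * 137.5
  fit2 <- fit_linearisation(ramp)
  expect_equal(fit1$a, fit2$a, tolerance = 1e-8)
  expect_equal(fit1$b, fit2$b, tolerance = 1e-8)
})

test_that("saturated ramp observations are excluded from the fit", {
  ramp <- oracle_ramp(unit_c_model())
  poisoned <- rbind(ramp,
                    data.frame(integration_ms = 4096, summed_counts = 1e9,
                               saturated = TRUE))
  fit <- fit_linearisation(poisoned)
  expect_lt(abs(fit$a - 0.14231), 1e-3)
  expect_lt(abs(fit$b - 1.06125), 1e-3)
})

test_that("degenerate ramps are rejected with a diagnostic", {
  expect_error(fit_linearisation(oracle_ramp(unit_c_model())[1:3, ]),
               "at least 4")
  narrow <- data.frame(integration_ms = c(10, 12, 14, 16),
                       summed_counts = c(10, 12, 14, 16), saturated = FALSE)
  expect_error(fit_linearisation(narrow), "octaves")
})

test_that("a noisy simulated octave ramp still fits with high R-squared", {
  cfg <- sensor_config(nonlin_a = 0.14231, nonlin_b = 1.06125)
  ramp <- simulate_linearisation_ramp(scene_flat(0.004), cfg, seed = 303)
  expect_true(any(ramp$saturated))   # ramped down from the saturation point
  fit <- fit_linearisation(ramp)
  expect_gte(fit$r_squared, 0.989)
})

test_that("one unit's coefficients still explain another unit's ramp well", {
  r <- expected_rates(2^(0:10))
  c_e <- lin_invert(r, unit_e_model())
  pred <- lin_apply(c_e, unit_c_model())
  r2 <- 1 - sum((pred - r)^2) / sum((r - mean(r))^2)
  expect_gte(r2, 0.99)
})

test_that("linearisation is odd, fixes zero, and inverts the count response", {
  m <- unit_c_model()
  expect_identical(linearise(0, m), 0)
  x <- c(0.5, 3, 17, 150, 600, 899)
  expect_equal(linearise(-x, m), -linearise(x, m))
  # generative round trip: ideal -> counts -> linearised == ideal
  v <- seq(0.01, 1, by = 0.01) * 900
  raw <- 900 * lin_invert(v / 900, m)
  expect_equal(linearise(raw, m), v, tolerance = 1e-9)
})

test_that("fitted responses are increasing, non-negative and anchored at one", {
  for (m in list(unit_c_model(), unit_e_model(), lin_model(5, 0.9))) {
    x <- seq(0, 1, by = 0.005)
    y <- lin_apply(x, m)
    expect_true(all(diff(y) > 0))
    expect_true(all(y >= 0))
    expect_equal(y[length(y)], 1)
    expect_equal(lin_invert(lin_apply(x, m), m), x, tolerance = 1e-9)
  }
})

test_that("a flat reference with a flat count rate gives flat unit sensitivity", {
  wmap <- wavelength_map(c(320, 2))
  cs <- count_spectrum(rep(120, 288), 10, 3)
  S <- derive_sensitivity(cs, scene_flat(0.5), wmap, "radiance")
  expect_equal(S$S, rep(1, 288))
  expect_identical(S$mode, "radiance")
})

test_that("scaling the reference rescales sensitivity before, not after, normalisation", {
  wmap <- wavelength_map(c(320, 2))
  set.seed(12)
  cs <- count_spectrum(200 + stats::runif(288, -20, 20), 10, 3)
  ref <- scene_flat(0.5)
  S1 <- derive_sensitivity(cs, ref, wmap, "radiance")
  S2 <- derive_sensitivity(cs, scene_scale(ref, 2), wmap, "radiance")
  expect_equal(S1$S, S2$S)  # peak-normalised output is scale invariant
  expect_error(derive_sensitivity(cs, scene_led(1), wmap, "radiance"),
               "strictly positive")
})

test_that("sensitivity derived from simulated data recovers the true curve", {
  cfg <- quiet_config()
  wmap <- wavelength_map(cfg$wavelength_coeffs, cfg$n_photosites)
  ref <- scene_flat(0.002)
  cs <- acquire(ref, exposure_plan(50, 3, config = cfg), cfg)
  cs_lin <- count_spectrum(linearise(cs, lin_model(cfg$nonlin_a, cfg$nonlin_b)),
                           cs$integration_ms, cs$n_scans)
  S <- derive_sensitivity(cs_lin, ref, wmap, "radiance")
  truth <- gaussian_smooth(cfg$true_sensitivity, 3)
  expect_lt(sqrt(mean((S$S - truth / max(truth))^2)), 0.01)
})

test_that("absolute scaling is the identity for a self-consistent standard and linear in it", {
  cfg <- quiet_config()
  wmap <- wavelength_map(cfg$wavelength_coeffs, cfg$n_photosites)
  ref <- scene_flat(0.002)
  cs <- acquire(ref, exposure_plan(50, 3, config = cfg), cfg)
  cs_lin <- count_spectrum(linearise(cs, lin_model(cfg$nonlin_a, cfg$nonlin_b)),
                           cs$integration_ms, cs$n_scans)
  S_rel <- derive_sensitivity(cs_lin, ref, wmap, "radiance")
  # a standard defined as exactly the conversion's own prediction: k = 1
  pred <- cs_lin$c / (S_rel$S * cs_lin$integration_ms * wmap$B)
  standard <- scene_spectrum(wmap$lambda, pred, "radiance")
  S_abs <- absolute_scale(S_rel, cs_lin, standard, wmap)
  expect_equal(S_abs$S, S_rel$S, tolerance = 1e-6)
  # a 10x brighter standard needs a 10x smaller sensitivity
  S_abs10 <- absolute_scale(S_rel, cs_lin, scene_scale(standard, 10), wmap)
  expect_equal(S_abs10$S, S_rel$S / 10, tolerance = 1e-6)
  expect_error(absolute_scale(S_rel, cs_lin,
                              scene_spectrum(c(300, 900), c(0, 0), "radiance"),
                              wmap),
               "zero")
})

test_that("cosine deviation is one for a Lambertian response and follows the degradation model", {
  th <- seq(0, 80, by = 10)
  ideal <- cosine_deviation(th, cos(th * pi / 180))
  expect_equal(ideal$deviation, rep(1, length(th)))

  sq <- cosine_deviation(c(0, 60), cos(c(0, 60) * pi / 180)^2)
  expect_equal(sq$deviation[2], 0.5)  # cos(60 deg) = 0.5

  cfg <- quiet_config()
  sw <- simulate_angle_sweep(0.05, th, corrector_quality = 0.8, config = cfg)
  rd <- sweep_readings(sw, cfg)
  dev <- cosine_deviation(rd$angle_deg, rd$reading)
  oracle <- 0.8 + 0.2 * cos(th * pi / 180)  # closed form of the mixture
  expect_equal(dev$deviation, oracle, tolerance = 0.01)

  expect_error(cosine_deviation(c(0, 90), c(1, 0)), "90")
  expect_error(cosine_deviation(c(10, 20), c(1, 1)), "0 degrees")
})
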