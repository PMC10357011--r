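test_that("bin widths are midpoint differences with one-sided ends", {
  wm_lin <- wavelength_map(c(320, 2))
  expect_equal(bin_widths(wm_lin), rep(2, 288))

  B3 <- ospra:::midpoint_bin_widths(c(400, 410, 430))
  expect_equal(B3, c(10, 15, 20))

  wm_quad <- wavelength_map(c(320, 1.5, 2e-3))
  expect_true(all(diff(bin_widths(wm_quad)) > 0))  # convex map widens bins
  expect_error(wavelength_map(c(320, -1)), "strictly increasing")
  # total width accounts for the range plus half of each end bin
  wm <- wavelength_map(c(320, 1.9, -4e-4))
  expect_equal(sum(wm$B),
               max(wm$lambda) - min(wm$lambda) + (wm$B[1] + wm$B[288]) / 2)
})

test_that("count-to-spectrum arithmetic follows counts / (S T B)", {
  # identity linearisation, S = 2, T = 10 ms, B = 5 nm, c = 100 -> 1
  calib <- calibration_record("U", c(320, 5), 1e12, 1, rep(2, 288), rep(2, 288))
  cs <- count_spectrum(rep(100, 288), 10, 3)
  sp <- counts_to_spectrum(cs, calib, "radiance", label = "unit arithmetic")
  expect_equal(sp$values, rep(1, 288), tolerance = 1e-9)
  expect_identical(sp$raw_counts, cs$c)
  expect_identical(sp$mode, "radiance")

  # doubling T on identical counts halves every value
  cs2 <- count_spectrum(rep(100, 288), 20, 3)
  sp2 <- counts_to_spectrum(cs2, calib, "radiance")
  expect_equal(sp2$values, sp$values / 2)

  # homogeneity for an identity response: counts x alpha -> values x alpha
  cs3 <- count_spectrum(rep(100, 288) * 3.5, 10, 3)
  sp3 <- counts_to_spectrum(cs3, calib, "radiance")
  expect_equal(sp3$values, 3.5 * sp$values, tolerance = 1e-9)

  bad <- calibration_record("U", c(320, 5), 1e12, 1, rep(2, 288), rep(2, 288))
  bad$S_r[7] <- 0
  expect_error(counts_to_spectrum(cs, bad, "radiance"), "positive")
})

test_that("negative calibrated values survive the conversion unclipped", {
  calib <- calibration_record("U", c(320, 5), 1e12, 1, rep(2, 288), rep(2, 288))
  c_p <- rep(c(-3, 4), length.out = 288)
  sp <- counts_to_spectrum(count_spectrum(c_p, 10, 3), calib, "radiance")
  expect_true(any(sp$values < 0))
  expect_equal(sign(sp$values), sign(c_p))
})

test_that("the full simulated chain recovers the scene within 2 percent in band", {
  for (cfg in list(quiet_config(),
                   quiet_config(nonlin_a = 0.14231, nonlin_b = 1.06125))) {
    calib <- default_calibration(cfg)
    sc <- scene_amoled(0.005)
    cs <- acquire(sc, exposure_plan(20, 10, config = cfg), cfg)
    sp <- counts_to_spectrum(cs, calib, "radiance")
    truth <- scene_value_at(sc, sp$lambda)
    in_band <- sp$lambda >= 420 & sp$lambda <= 700
    rms <- sqrt(mean((sp$values[in_band] - truth[in_band])^2)) / max(truth)
    expect_lt(rms, 0.02)
  }
})

test_that("the fixed dark offset subtracts 0.5 or 0.2 counts by mode", {
  cs <- count_spectrum(c(1.0, 0.5, rep(2, 286)), 10, 3)
  expect_equal(dark_offset_correct(cs, "radiance")$c[1:2], c(0.5, 0.0))
  cs_i <- count_spectrum(c(0.2, rep(1, 287)), 10, 3)
  expect_equal(dark_offset_correct(cs_i, "irradiance")$c[1], 0.0)
  expect_equal(dark_offset_correct(cs, "radiance", offset = 0)$c, cs$c)
})

test_that("Gaussian smoothing preserves constants and reduces to a kernel on an impulse", {
  expect_equal(gaussian_smooth(rep(4.2, 100), 3), rep(4.2, 100))
  x <- stats::rnorm(50)
  expect_identical(gaussian_smooth(x, 0), x)
  expect_error(gaussian_smooth(x, -1), "non-negative")

  imp <- c(rep(0, 50), 1, rep(0, 50))
  sm <- gaussian_smooth(imp, 3)
  r <- ceiling(4 * 3)
  kernel <- exp(-0.5 * ((-r:r) / 3)^2)
  kernel <- kernel / sum(kernel)
  expect_equal(sm[(51 - r):(51 + r)], kernel, tolerance = 1e-6)
})

test_that("area normalisation fixes the in-band area at one and is idempotent", {
  cfg <- quiet_config()
  calib <- default_calibration(cfg)
  cs <- acquire(scene_amoled(0.005), exposure_plan(20, 3, config = cfg), cfg)
  sp <- counts_to_spectrum(cs, calib, "radiance")

  nz <- normalize_area(sp)
  B <- ospra:::midpoint_bin_widths(nz$lambda)
  in_band <- nz$lambda >= 425 & nz$lambda <= 650
  expect_lt(abs(sum(nz$values[in_band] * B[in_band]) - 1), 1e-9)

  expect_equal(normalize_area(nz)$values, nz$values)  # idempotent
  sp10 <- sp
  sp10$values <- sp$values * 10
  expect_equal(normalize_area(sp10)$values, nz$values)  # scale invariant
  zero <- sp
  zero$values <- rep(0, length(sp$values))
  expect_error(normalize_area(zero), "zero")
  expect_error(normalize_area(sp, 1000, 1100), "overlap")
})

test_that("re-processing stored raw counts reproduces saved values bit for bit", {
  cfg <- quiet_config()
  calib <- default_calibration(cfg)
  cs <- acquire(scene_amoled(0.005), exposure_plan(20, 3, config = cfg), cfg)
  sp <- counts_to_spectrum(cs, calib, "radiance")
  again <- counts_to_spectrum(
    count_spectrum(sp$raw_counts, sp$integration_ms, sp$n_scans, sp$n_saturated),
    calib, "radiance")
  expect_identical(again$values, sp$values)
})

test_that("stray light inflates relative near-IR energy and the offset reduces it", {
  sc <- scene_amoled(6e-7)
  base_cfg <- sensor_config(stray_light_fraction = 0)
  photo <- ospra:::expected_photo_counts(sc, 5000, "radiance", base_cfg)
  frac <- 0.5 * 288 / sum(photo)  # pedestal of about half a count
  cfg <- sensor_config(stray_light_fraction = frac)
  calib <- default_calibration(cfg)
  nir_share <- function(cs) {
    sp <- normalize_area(smooth_spectrum(counts_to_spectrum(cs, calib, "radiance"), 3))
    nir <- sp$lambda > 740
    sum(sp$values[nir] * ospra:::midpoint_bin_widths(sp$lambda)[nir])
  }
  set.seed(7)
  cs_stray <- acquire(sc, exposure_plan(5000, 3, config = cfg), cfg)
  cs_clean <- acquire(sc, exposure_plan(5000, 3, config = base_cfg), base_cfg)
  raw_share <- nir_share(cs_stray)
  corrected <- nir_share(dark_offset_correct(cs_stray, "radiance"))
  expect_gt(raw_share, nir_share(cs_clean))  # the artefact inflates near-IR
  expect_lt(corrected, raw_share)            # the fixed offset pulls it back
})
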