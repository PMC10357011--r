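#' Simulate one ADC readout of the line sensor
#'
#' Generative model of a single exposure. With the shutter closed the
#' expected counts are the dark model alone. With the shutter open the
#' expected ideal (linear) photo-signal at photosite p is
#' `true_sensitivity[p] * scene(lambda_p) * B_p * integration_ms`; the
#' count nonlinearity is applied in the generative direction
#' (`counts = ceiling * f^-1(ideal / ceiling)`), a stray-light pedestal
#' proportional to the total in-band photo-signal is spread uniformly
#' across all photosites, shot noise (Poisson) and Gaussian dark/read
#' noise are added, and the result is quantised and clipped to the ADC
#' range `[0, adc_levels - 1]`. Counts at or above `usable_levels` are
#' treated as saturated by downstream consumers.
#'
#' @param scene A [scene_spectrum()] whose mode matches the open shutter
#'   state; ignored (may be `NULL`) when `shutter = "closed"`.
#' @param integration_ms Integration time in ms, within the configured range.
#' @param shutter `"closed"`, `"radiance"` or `"irradiance"`.
#' @param config A [sensor_config()].
#' @param seed Optional integer seed for this frame (defaults to the
#'   session RNG stream, or `config$rng_seed` if set).
#' @return An object of class `raw_frame`: integer `counts`,
#'   `integration_ms`, `shutter`.
#' @export
#' @examples
#' cfg <- sensor_config(dark_sd = 0, read_noise_sd = 0, shot_noise = FALSE)
#' fr <- simulate_frame(scene_flat(0.01), 10, "radiance", cfg)
#' range(fr$counts)
simulate_frame <- function(scene, integration_ms,
                           shutter = c("radiance", "irradiance", "closed"),
                           config = sensor_config(), seed = NULL) {
  shutter <- match.arg(shutter)
  stopifnot(inherits(config, "sensor_config"))
  if (integration_ms < config$min_integration_ms ||
      integration_ms > config$max_integration_ms) {
    stop(sprintf("integration time %g ms outside permitted range [%g, %g] ms",
                 integration_ms, config$min_integration_ms,
                 config$max_integration_ms))
  }
  if (shutter != "closed") {
    if (!inherits(scene, "scene_spectrum")) {
      stop("an open-shutter frame requires a scene_spectrum")
    }
    if (scene$mode != shutter) {
      stop(sprintf("scene mode '%s' does not match shutter state '%s'",
                   scene$mode, shutter))
    }
  }
  if (is.null(seed)) seed <- config$rng_seed
  if (!is.null(seed)) set.seed(seed)

  expected_photo <- expected_photo_counts(scene, integration_ms, shutter, config)
  n <- config$n_photosites
  photo <- if (config$shot_noise) {
    stats::rpois(n, expected_photo)
  } else {
    expected_photo
  }
  dark <- config$dark_mean
  if (config$dark_sd > 0) dark <- dark + stats::rnorm(n, 0, config$dark_sd)
  read <- if (config$read_noise_sd > 0) stats::rnorm(n, 0, config$read_noise_sd) else 0
  counts <- round(photo + dark + read)
  counts <- pmin(pmax(counts, 0), config$adc_levels - 1L)
  structure(list(counts = as.integer(counts),
                 integration_ms = integration_ms,
                 shutter = shutter),
            class = "raw_frame")
}

# expected photo-signal (above the dark level, before noise/quantisation)
expected_photo_counts <- function(scene, integration_ms, shutter, config) {
  n <- config$n_photosites
  if (shutter == "closed") return(rep(0, n))
  wmap <- wavelength_map(config$wavelength_coeffs, n)
  scene_p <- scene_value_at(scene, wmap$lambda)
  ideal <- config$true_sensitivity * scene_p * wmap$B * integration_ms
  ceiling_cts <- config$usable_levels
  model <- lin_model(config$nonlin_a, config$nonlin_b)
  photo <- ceiling_cts * lin_invert(ideal / ceiling_cts, model)
  if (config$stray_light_fraction > 0) {
    photo <- photo + config$stray_light_fraction * sum(photo) / n
  }
  photo
}

#' @export
print.raw_frame <- function(x, ...) {
  cat(sprintf("<raw_frame> shutter=%s, %g ms, counts %d-%d\n",
              x$shutter, x$integration_ms, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Simulate a cosine-corrector angle sweep
#'
#' Emulates the bench protocol for evaluating a cosine corrector: a stable
#' narrowband LED point source is swung around the irradiance port from
#' normal incidence towards grazing angles while the diffuser's levelled
#' surface stays fixed. An ideal (Lambertian) diffuser transmits a signal
#' proportional to cos(theta); an imperfect one is modelled as the
#' sub-Lambertian mixture
#' `corrector_quality * cos(theta) + (1 - corrector_quality) * cos(theta)^2`.
#'
#' @param led_intensity Peak spectral irradiance of the LED at normal
#'   incidence (W m^-2 nm^-1); must be non-negative.
#' @param angles_deg Incidence angles in degrees, each in `[0, 90)`.
#' @param corrector_quality Diffuser quality in `[0, 1]`; 1 is Lambertian.
#' @param config A [sensor_config()].
#' @param integration_ms Integration time used for every angle.
#' @param n_scans Light (and dark) frames per angle.
#' @param seed Optional integer seed.
#' @return A list with one element per angle: `angle_deg`, `light`
#'   (list of `raw_frame`), `dark` (list of `raw_frame`).
#' @seealso [sweep_readings()], [cosine_deviation()]
#' @export
simulate_angle_sweep <- function(led_intensity, angles_deg,
                                 corrector_quality = 1,
                                 config = sensor_config(),
                                 integration_ms = 10, n_scans = 3,
                                 seed = NULL) {
  stopifnot(led_intensity >= 0,
            corrector_quality >= 0, corrector_quality <= 1)
  if (any(angles_deg < 0 | angles_deg >= 90)) {
    stop("angles must lie in [0, 90) degrees")
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(angles_deg, function(theta) {
    ct <- cos(theta * pi / 180)
    transmitted <- corrector_quality * ct + (1 - corrector_quality) * ct^2
    sc <- scene_led(led_intensity * transmitted, mode = "irradiance")
    list(
      angle_deg = theta,
      light = lapply(seq_len(n_scans), function(i)
        simulate_frame(sc, integration_ms, "irradiance", config)),
      dark = lapply(seq_len(n_scans), function(i)
        simulate_frame(NULL, integration_ms, "closed", config))
    )
  })
}

#' Summarise an angle sweep into per-angle scalar readings
#'
#' Averages light and dark frames per angle, subtracts the dark mean and
#' sums the dark-subtracted counts over photosites inside the LED's
#' emission band, yielding the scalar signal used by [cosine_deviation()].
#'
#' @param sweep Output of [simulate_angle_sweep()].
#' @param config The [sensor_config()] used for the sweep.
#' @param band_nm Two-element wavelength band to sum over, nm.
#' @return A data frame with columns `angle_deg` and `reading`.
#' @export
sweep_readings <- function(sweep, config, band_nm = c(540, 640)) {
  wmap <- wavelength_map(config$wavelength_coeffs, config$n_photosites)
  in_band <- wmap$lambda >= band_nm[1] & wmap$lambda <= band_nm[2]
  rows <- lapply(sweep, function(s) {
    l <- rowMeans(vapply(s$light, `[[`, numeric(config$n_photosites), "counts"))
    d <- rowMeans(vapply(s$dark, `[[`, numeric(config$n_photosites), "counts"))
    data.frame(angle_deg = s$angle_deg, reading = sum((l - d)[in_band]))
  })
  do.call(rbind, rows)
}
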