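#' Sensor configuration for the simulated micro-spectrometer
#'
#' Describes one simulated unit: a 288-photosite CMOS line sensor read
#' through a 10-bit ADC, with a mechanical shutter offering closed,
#' radiance and irradiance apertures. The ADC offers `adc_levels` linear
#' levels but the sensor's output voltage range limits the usable span to
#' about `usable_levels` counts, which sets the saturation ceiling used by
#' exposure planning and by saturation accounting.
#'
#' @param n_photosites Number of photosites on the line sensor.
#' @param adc_levels Number of linear ADC levels (10-bit converter: 1024).
#' @param usable_levels Saturation ceiling in counts; counts at or above
#'   this value underestimate the flux and are flagged as saturated.
#' @param min_integration_ms,max_integration_ms Permitted integration-time
#'   range in milliseconds. Exposures beyond 30 s are not supported.
#' @param dark_mean Per-photosite mean dark level in counts (scalar values
#'   are recycled across photosites).
#' @param dark_sd Per-photosite dark-noise standard deviation in counts.
#' @param read_noise_sd Read-noise standard deviation in counts.
#' @param shot_noise Logical; draw the photo-signal from a Poisson law
#'   before quantisation. Set `FALSE` (with `dark_sd = 0` and
#'   `read_noise_sd = 0`) for a fully deterministic sensor.
#' @param true_sensitivity Per-photosite responsivity in
#'   counts ms^-1 per (W sr^-1 m^-2 nm^-1) nm; the expected linear count
#'   rate at photosite p is `true_sensitivity[p] * scene(lambda_p) * B_p`.
#'   Defaults to a smooth broadband curve peaking near 580 nm with roughly
#'   two-thirds relative sensitivity in the near UV.
#' @param nonlin_a,nonlin_b Ground-truth coefficients of the count
#'   nonlinearity, in the same two-coefficient parametrisation used by
#'   [lin_model()]. The default (`a = 1e12`, `b = 1`) is numerically an
#'   identity response, i.e. a well-linearised sensor; set the coefficients
#'   of a fitted unit to emulate the compressive low-count response.
#' @param wavelength_coeffs Up to six polynomial coefficients mapping
#'   photosite index (0-based) to wavelength in nm; shorter vectors are
#'   zero-padded. The default spans roughly 320-850 nm with mild curvature.
#' @param stray_light_fraction Fraction of the band-summed photo-signal
#'   scattered uniformly across all photosites. Stray light is present with
#'   the shutter open only, so it is not removed by closed-shutter darks.
#' @param rng_seed Optional integer seed recorded with the configuration
#'   and used by the simulator when no explicit seed is given.
#'
#' @return An object of class `sensor_config` (a validated list).
#' @seealso [simulate_frame()], [wavelength_map()], [dynamic_range()]
#' @export
#' @examples
#' cfg <- sensor_config()
#' dynamic_range(cfg)
sensor_config <- function(n_photosites = 288L,
                          adc_levels = 1024L,
                          usable_levels = 900L,
                          min_integration_ms = 1,
                          max_integration_ms = 30000,
                          dark_mean = 30,
                          dark_sd = 1,
                          read_noise_sd = 0.5,
                          shot_noise = TRUE,
                          true_sensitivity = NULL,
                          nonlin_a = 1e12,
                          nonlin_b = 1,
                          wavelength_coeffs = c(320, 1.9, -4e-4),
                          stray_light_fraction = 0,
                          rng_seed = NULL) {
  n_photosites <- as.integer(n_photosites)
  wavelength_coeffs <- pad_coeffs(wavelength_coeffs)
  if (length(dark_mean) == 1L) dark_mean <- rep(dark_mean, n_photosites)
  if (is.null(true_sensitivity)) {
    # bilobed Gaussian: ~2/3 relative sensitivity at 320 nm, peak near
    # 560 nm, falling steeply towards the near infrared
    lambda <- polyval_sites(wavelength_coeffs, n_photosites)
    sig <- ifelse(lambda < 560, 270, 120)
    true_sensitivity <- 1000 * exp(-0.5 * ((lambda - 560) / sig)^2)
  }
  cfg <- structure(list(
    n_photosites = n_photosites,
    adc_levels = as.integer(adc_levels),
    usable_levels = as.integer(usable_levels),
    min_integration_ms = min_integration_ms,
    max_integration_ms = max_integration_ms,
    dark_mean = dark_mean,
    dark_sd = dark_sd,
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    true_sensitivity = true_sensitivity,
    nonlin_a = nonlin_a,
    nonlin_b = nonlin_b,
    wavelength_coeffs = wavelength_coeffs,
    stray_light_fraction = stray_light_fraction,
    rng_seed = rng_seed
  ), class = "sensor_config")
  validate_sensor_config(cfg)
}

validate_sensor_config <- function(cfg) {
  stopifnot(
    cfg$n_photosites >= 2L,
    cfg$adc_levels >= 2L,
    cfg$usable_levels > 0L,
    cfg$usable_levels <= cfg$adc_levels - 1L,
    cfg$min_integration_ms > 0,
    cfg$min_integration_ms <= cfg$max_integration_ms,
    length(cfg$dark_mean) == cfg$n_photosites,
    all(cfg$dark_mean >= 0),
    cfg$dark_sd >= 0,
    cfg$read_noise_sd >= 0,
    length(cfg$true_sensitivity) == cfg$n_photosites,
    all(cfg$true_sensitivity >= 0),
    cfg$nonlin_a > 0,
    cfg$nonlin_b > 0,
    cfg$stray_light_fraction >= 0,
    length(cfg$wavelength_coeffs) == 6L
  )
  lambda <- polyval_sites(cfg$wavelength_coeffs, cfg$n_photosites)
  if (any(diff(lambda) <= 0)) {
    stop("wavelength map must be strictly increasing over photosite index")
  }
  cfg
}

#' @export
print.sensor_config <- function(x, ...) {
  lambda <- polyval_sites(x$wavelength_coeffs, x$n_photosites)
  cat(sprintf("<sensor_config> %d photosites, %d ADC levels (ceiling %d)\n",
              x$n_photosites, x$adc_levels, x$usable_levels))
  cat(sprintf("  wavelengths %.1f-%.1f nm; integration %g-%g ms\n",
              min(lambda), max(lambda),
              x$min_integration_ms, x$max_integration_ms))
  cat(sprintf("  dark %.1f +/- %.2f counts, read noise %.2f, shot noise %s\n",
              mean(x$dark_mean), x$dark_sd, x$read_noise_sd,
              if (x$shot_noise) "on" else "off"))
  invisible(x)
}

# pad a coefficient vector to the fixed polynomial degree (6 coefficients)
pad_coeffs <- function(coeffs) {
  stopifnot(is.numeric(coeffs), length(coeffs) >= 1L, length(coeffs) <= 6L)
  c(coeffs, rep(0, 6L - length(coeffs)))
}

# evaluate the wavelength polynomial at 0-based photosite indices
polyval_sites <- function(coeffs, n_photosites) {
  p <- seq_len(n_photosites) - 1
  drop(outer(p, 0:5, `^`) %*% coeffs)
}

#' Theoretical single-exposure dynamic range
#'
#' The ratio of the saturation ceiling to one ADC count: the brightest and
#' faintest signals distinguishable within a single exposure. Averaging
#' over multiple exposures improves on this considerably, and noisy
#' low-light conditions reduce it.
#'
#' @param config A [sensor_config()].
#' @return The dynamic-range ratio (900 for the default configuration).
#' @export
dynamic_range <- function(config) {
  stopifnot(inherits(config, "sensor_config"))
  config$usable_levels / 1
}

#' Write or read a sensor configuration as plain text
#'
#' Serialises a [sensor_config()] to a simple `key: value` text file
#' (vectors comma-separated). The round trip `read_sensor_config(
#' write_sensor_config(cfg, path))` reproduces the configuration.
#'
#' @param config A [sensor_config()].
#' @param path File path.
#' @return `write_sensor_config` returns `path` invisibly;
#'   `read_sensor_config` returns a `sensor_config`.
#' @export
write_sensor_config <- function(config, path) {
  stopifnot(inherits(config, "sensor_config"))
  fields <- config[!vapply(config, is.null, logical(1))]
  lines <- vapply(names(fields), function(nm) {
    v <- fields[[nm]]
    val <- if (is.logical(v)) {
      as.character(v)
    } else {
      paste(sprintf("%.17g", as.numeric(v)), collapse = ",")
    }
    paste0(nm, ": ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sensor_config
#' @export
read_sensor_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  args <- stats::setNames(
    lapply(kv, function(x) {
      val <- trimws(x[[2]])
      if (val %in% c("TRUE", "FALSE")) return(as.logical(val))
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }),
    vapply(kv, function(x) trimws(x[[1]]), character(1))
  )
  do.call(sensor_config, args[names(args) %in% names(formals(sensor_config))])
}
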