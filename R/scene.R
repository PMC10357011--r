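#' Scene spectra: the "true" light field imaged by the simulator
#'
#' A `scene_spectrum` holds spectral radiance (W sr^-1 m^-2 nm^-1) or
#' spectral irradiance (W m^-2 nm^-1) on a strictly increasing wavelength
#' grid. Scenes are the ground truth against which every simulated
#' acquisition and every recovery test is checked.
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing.
#' @param values Non-negative spectral values, same length.
#' @param mode `"radiance"` or `"irradiance"`.
#' @return An object of class `scene_spectrum`.
#' @export
#' @examples
#' sc <- scene_flat(0.01)
#' scene_value_at(sc, c(400, 555, 700))
scene_spectrum <- function(wavelengths, values, mode = c("radiance", "irradiance")) {
  mode <- match.arg(mode)
  stopifnot(length(wavelengths) == length(values), length(values) >= 2L)
  if (any(diff(wavelengths) <= 0)) stop("scene wavelengths must be strictly increasing")
  if (any(values < 0)) stop("scene values must be non-negative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values),
                 mode = mode),
            class = "scene_spectrum")
}

#' @export
print.scene_spectrum <- function(x, ...) {
  cat(sprintf("<scene_spectrum> %s, %d points, %.0f-%.0f nm, peak %.4g\n",
              x$mode, length(x$values), min(x$wavelengths), max(x$wavelengths),
              max(x$values)))
  invisible(x)
}

#' Linear interpolation of a scene onto arbitrary wavelengths (zero outside
#' the tabulated range).
#' @param scene A [scene_spectrum()].
#' @param wavelengths_nm Wavelengths at which to evaluate, in nm.
#' @return Numeric vector of spectral values.
#' @export
scene_value_at <- function(scene, wavelengths_nm) {
  stopifnot(inherits(scene, "scene_spectrum"))
  stats::approx(scene$wavelengths, scene$values, xout = wavelengths_nm,
                yleft = 0, yright = 0)$y
}

#' Convenience scene constructors
#'
#' `scene_flat()` is spectrally flat over `range_nm`; `scene_amoled()`
#' emulates a white AMOLED display with three clearly defined emission
#' peaks (blue, green, red OLED primaries); `scene_led()` is a single
#' narrowband LED line, by default a PC-amber LED near 590 nm.
#'
#' @param level Spectral value of the flat scene.
#' @param range_nm Two-element wavelength range, nm.
#' @param mode `"radiance"` or `"irradiance"`.
#' @param brightness Peak spectral value of the brightest primary.
#' @param intensity Peak spectral value of the LED line.
#' @param peak_nm,width_nm Centre and Gaussian sigma of the LED line, nm.
#' @return A [scene_spectrum()].
#' @export
scene_flat <- function(level, range_nm = c(300, 900),
                       mode = c("radiance", "irradiance")) {
  wl <- seq(range_nm[1], range_nm[2], by = 1)
  scene_spectrum(wl, rep(level, length(wl)), match.arg(mode))
}

#' @rdname scene_flat
#' @export
scene_amoled <- function(brightness = 0.01, mode = c("radiance", "irradiance")) {
  wl <- seq(300, 900, by = 1)
  v <- brightness * (0.75 * exp(-0.5 * ((wl - 455) / 12)^2) +
                     1.00 * exp(-0.5 * ((wl - 528) / 18)^2) +
                     0.85 * exp(-0.5 * ((wl - 625) / 14)^2))
  scene_spectrum(wl, v, match.arg(mode))
}

#' @rdname scene_flat
#' @export
scene_led <- function(intensity = 0.05, peak_nm = 590, width_nm = 8,
                      mode = c("radiance", "irradiance")) {
  wl <- seq(300, 900, by = 1)
  scene_spectrum(wl, intensity * exp(-0.5 * ((wl - peak_nm) / width_nm)^2),
                 match.arg(mode))
}

#' Scale a scene by a non-negative factor.
#' @param scene A [scene_spectrum()].
#' @param factor Non-negative scalar.
#' @return A [scene_spectrum()].
#' @export
scene_scale <- function(scene, factor) {
  stopifnot(inherits(scene, "scene_spectrum"), factor >= 0)
  scene_spectrum(scene$wavelengths, scene$values * factor, scene$mode)
}
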