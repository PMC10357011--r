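#' Luminous-efficiency weighting on a unit's wavelength grid
#'
#' Photometric summaries (luminance in cd m^-2, illuminance in lux)
#' weight the measured spectrum by the human photopic luminous-efficiency
#' function. The curve is generated analytically on each unit's own
#' photosite wavelengths so the weighting matches the unit's spectral
#' response exactly. The analytic form is a sum of two piecewise
#' (bilobed) Gaussians fitted to the photopic efficiency curve:
#' it peaks at ~555 nm with value ~1, is unimodal, and is set to zero
#' outside the 360-830 nm photopic support.
#'
#' @param wmap A [wavelength_map()].
#' @param K_m Maximum luminous efficacy in lm W^-1 (683 by convention;
#'   configurable should a different photometric normalisation be wanted).
#' @return An object of class `luminosity_function`: per-photosite
#'   `ybar`, the grid `lambda`, bin widths `B` and the constant `K_m`.
#' @export
#' @examples
#' lf <- luminosity_on_grid(wavelength_map(c(320, 1.9, -4e-4)))
#' max(lf$ybar)
luminosity_on_grid <- function(wmap, K_m = 683) {
  stopifnot(inherits(wmap, "wavelength_map"), K_m > 0)
  structure(list(ybar = photopic_ybar(wmap$lambda),
                 lambda = wmap$lambda, B = wmap$B, K_m = K_m),
            class = "luminosity_function")
}

#' @rdname luminosity_on_grid
#' @param wavelengths_nm Wavelengths at which to evaluate the analytic
#'   photopic curve, nm.
#' @export
photopic_ybar <- function(wavelengths_nm) {
  wl <- as.numeric(wavelengths_nm)
  # bilobed-Gaussian analytic approximation of the photopic curve:
  # amplitude, centre (nm), left sigma, right sigma
  g <- function(wl, amp, mu, s_left, s_right) {
    s <- ifelse(wl < mu, s_left, s_right)
    amp * exp(-0.5 * ((wl - mu) / s)^2)
  }
  y <- g(wl, 0.821, 568.8, 46.9, 40.5) + g(wl, 0.286, 530.9, 16.3, 31.1)
  y[wl < 360 | wl > 830] <- 0
  pmin(pmax(y, 0), 1)
}

#' @export
print.luminosity_function <- function(x, ...) {
  cat(sprintf("<luminosity_function> %d photosites, peak ybar %.4f at %.0f nm, K_m = %g lm/W\n",
              length(x$ybar), max(x$ybar), x$lambda[which.max(x$ybar)], x$K_m))
  invisible(x)
}

#' Luminance or illuminance of a calibrated spectrum
#'
#' Integrates the spectrum against the luminous-efficiency weighting:
#' `K_m * sum(value_p * ybar_p * B_p)`. For a radiance spectrum the
#' result is luminance in cd m^-2; for an irradiance spectrum it is
#' illuminance in lux (lm m^-2).
#'
#' @param spectrum A [calibrated_spectrum()].
#' @param lf A [luminosity_function()] on the same wavelength grid.
#' @return A single number (cd m^-2 or lux according to the mode).
#' @export
luminance <- function(spectrum, lf) {
  stopifnot(inherits(spectrum, "calibrated_spectrum"),
            inherits(lf, "luminosity_function"))
  if (length(lf$ybar) != length(spectrum$values) ||
      max(abs(lf$lambda - spectrum$lambda)) > 1e-6) {
    stop("luminosity function grid does not match the spectrum's wavelengths")
  }
  lf$K_m * sum(spectrum$values * lf$ybar * lf$B)
}
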