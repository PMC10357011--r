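#' Photosite-to-wavelength mapping and spectral bin widths
#'
#' Each photosite's peak wavelength is described by a degree-5 polynomial
#' in the (0-based) photosite index, with coefficients supplied per unit
#' (shorter coefficient vectors are zero-padded). The spectral bin width
#' B_p of a photosite is the wavelength interval it represents: half the
#' distance between its neighbours for interior sites, one-sided
#' differences at the two ends. Bin widths convert per-nm spectral
#' densities to per-bin energy.
#'
#' @param coeffs Up to 6 polynomial coefficients (nm per index power).
#' @param n_photosites Number of photosites (default 288).
#' @return `wavelength_map()` returns an object of class `wavelength_map`
#'   with `coeffs`, per-photosite `lambda` (nm) and bin widths `B` (nm);
#'   `bin_widths()` returns the numeric vector `B`.
#' @export
#' @examples
#' wm <- wavelength_map(c(320, 2))  # uniform 2 nm grid
#' range(wm$B)
wavelength_map <- function(coeffs, n_photosites = 288L) {
  coeffs <- pad_coeffs(coeffs)
  lambda <- polyval_sites(coeffs, n_photosites)
  if (any(diff(lambda) <= 0)) {
    stop("wavelength map must be strictly increasing over photosite index")
  }
  structure(list(coeffs = coeffs, lambda = lambda,
                 B = midpoint_bin_widths(lambda)),
            class = "wavelength_map")
}

#' @rdname wavelength_map
#' @param wmap A `wavelength_map`.
#' @export
bin_widths <- function(wmap) {
  stopifnot(inherits(wmap, "wavelength_map"))
  wmap$B
}

midpoint_bin_widths <- function(lambda) {
  n <- length(lambda)
  stopifnot(n >= 2L)
  B <- numeric(n)
  B[1] <- lambda[2] - lambda[1]
  B[n] <- lambda[n] - lambda[n - 1]
  if (n > 2L) B[2:(n - 1)] <- (lambda[3:n] - lambda[1:(n - 2)]) / 2
  B
}

#' @export
print.wavelength_map <- function(x, ...) {
  cat(sprintf("<wavelength_map> %d photosites, %.1f-%.1f nm, bins %.2f-%.2f nm\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$B), max(x$B)))
  invisible(x)
}
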