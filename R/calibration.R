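#' Band-summed counts for linearisation ramps
#'
#' Sums dark-subtracted counts over all photosites whose peak wavelength
#' lies inside the (inclusive) band, by default 380-780 nm — the
#' approximate emission range of the AMOLED screen used as the stable
#' ramp source.
#'
#' @param counts A [count_spectrum()] or numeric vector.
#' @param wmap A [wavelength_map()].
#' @param lo_nm,hi_nm Band limits in nm (inclusive).
#' @return The scalar band sum.
#' @export
summed_band_counts <- function(counts, wmap, lo_nm = 380, hi_nm = 780) {
  stopifnot(inherits(wmap, "wavelength_map"))
  c_p <- if (inherits(counts, "count_spectrum")) counts$c else as.numeric(counts)
  stopifnot(length(c_p) == length(wmap$lambda))
  in_band <- wmap$lambda >= lo_nm & wmap$lambda <= hi_nm
  if (!any(in_band)) {
    stop(sprintf("no photosites fall inside the band [%g, %g] nm", lo_nm, hi_nm))
  }
  sum(c_p[in_band])
}

#' Expected linear count rates for an integration ramp
#'
#' For a stable source the expected linear count rate is proportional to
#' the exposure time; rates are rescaled so the largest equals 1, making
#' ramps comparable between units.
#'
#' @param integrations_ms Positive exposure times, ms.
#' @return Numeric vector with `max(.) == 1`.
#' @export
#' @examples
#' expected_rates(c(1, 2, 4))  # 0.25 0.5 1
expected_rates <- function(integrations_ms) {
  if (length(integrations_ms) == 0L) stop("empty integration ramp")
  stopifnot(all(integrations_ms > 0))
  integrations_ms / max(integrations_ms)
}

#' Fit the two-coefficient linearisation model to an exposure ramp
#'
#' Measurements of a stable source over octave-stepped integration times
#' give pairs of band-summed counts and expected linear rates. Both axes
#' are scaled to max = 1 (saturated observations are excluded first, so
#' the normalisation point is the largest unsaturated ramp step), and the
#' response `r = f(c; a, b)` of [lin_model()] is fitted by nonlinear
#' least squares (Levenberg-Marquardt, with `a` optimised on the log
#' scale and a coarse multi-start fallback).
#'
#' @param ramp A data frame with columns `integration_ms`,
#'   `summed_counts` and logical `saturated`.
#' @return A [lin_model()] carrying the fit's coefficient of
#'   determination in `$r_squared`.
#' @export
#' @examples
#' truth <- lin_model(0.14231, 1.06125)
#' t_ms <- 2^(0:10)
#' r <- expected_rates(t_ms)
#' ramp <- data.frame(integration_ms = t_ms,
#'                    summed_counts = 5e4 * lin_invert(r, truth),
#'                    saturated = FALSE)
#' fit_linearisation(ramp)
fit_linearisation <- function(ramp) {
  stopifnot(is.data.frame(ramp),
            all(c("integration_ms", "summed_counts", "saturated") %in% names(ramp)))
  ok <- !ramp$saturated & is.finite(ramp$summed_counts) & ramp$summed_counts > 0
  ramp <- ramp[ok, , drop = FALSE]
  if (nrow(ramp) < 4L) {
    stop("linearisation fit needs at least 4 unsaturated ramp observations")
  }
  span <- max(ramp$integration_ms) / min(ramp$integration_ms)
  if (span < 8) {
    stop(sprintf(paste0("linearisation ramp spans only %.2f octaves; ",
                        "at least 3 octaves are required"), log2(span)))
  }
  c_norm <- ramp$summed_counts / max(ramp$summed_counts)
  r <- expected_rates(ramp$integration_ms)

  fit_once <- function(loga0, b0) {
    loga0 <- unname(loga0)
    b0 <- unname(b0)
    tryCatch(
      minpack.lm::nlsLM(
        r ~ log1p(c_norm^b / exp(loga)) / log1p(1 / exp(loga)),
        start = list(loga = loga0, b = b0),
        lower = c(loga = -20, b = 0.05),
        upper = c(loga = 30, b = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  # published-coefficient start first, then a coarse grid
  starts <- rbind(c(log(0.14), 1.06),
                  as.matrix(expand.grid(loga = c(-4, -1, 2, 6, 12),
                                        b = c(0.7, 1, 1.4))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- fit_once(starts[i, 1], starts[i, 2])
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("linearisation fit failed to converge from all starts")
  est <- coef(best)
  ss_res <- deviance(best)
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot <= 0) stop("degenerate ramp: expected rates have no spread")
  lin_model(exp(est[["loga"]]), est[["b"]], r_squared = 1 - ss_res / ss_tot)
}

#' Simulate a linearisation exposure ramp
#'
#' Runs the bench protocol for linearisation calibration against the
#' simulator: a stable broadband source measured over one-octave
#' integration steps, ramped down from the saturation point to the
#' minimum exposure and back up (ramping both ways guards against source
#' drift on real hardware). Each step is a dark-subtracted, scan-averaged
#' acquisition; its band-summed counts and saturation state form one ramp
#' observation.
#'
#' @param scene A [scene_spectrum()]; should saturate the sensor at the
#'   top of the ramp.
#' @param config A [sensor_config()].
#' @param t_min_ms,t_max_ms Ramp limits, ms (octave-stepped).
#' @param n_scans Scans per step (default: the scan-count rule).
#' @param seed Optional integer seed.
#' @return A data frame with columns `integration_ms`, `summed_counts`,
#'   `saturated`, suitable for [fit_linearisation()].
#' @export
simulate_linearisation_ramp <- function(scene, config = sensor_config(),
                                        t_min_ms = 1, t_max_ms = 128,
                                        n_scans = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config$rng_seed <- NULL
  steps <- 2^(0:floor(log2(t_max_ms / t_min_ms))) * t_min_ms
  times <- c(rev(steps), steps)  # down from saturation, then back up
  wmap <- wavelength_map(config$wavelength_coeffs, config$n_photosites)
  rows <- lapply(times, function(t) {
    ns <- if (is.null(n_scans)) choose_scan_count(t) else n_scans
    cs <- acquire(scene, exposure_plan(t, ns, config = config), config)
    data.frame(integration_ms = t,
               summed_counts = summed_band_counts(cs, wmap),
               saturated = cs$n_saturated > 0L)
  })
  do.call(rbind, rows)
}

#' Relative spectral-sensitivity calibration
#'
#' Divides the measured, linearised count rate per nm at each photosite
#' by a reference spectrum of known shape (resampled onto the photosite
#' wavelengths by linear interpolation), smooths the ratio with a
#' Gaussian filter (sigma = 3 photosites) and rescales to peak = 1.
#' The result is the unit's relative spectral sensitivity, a product of
#' optical transmission, diffraction-grating efficiency and CMOS
#' sensitivity.
#'
#' @param measured A [count_spectrum()] of the reference source whose
#'   counts are already linearised and unsaturated.
#' @param reference A [scene_spectrum()]: the reference source's known
#'   spectrum, strictly positive across the instrument band.
#' @param wmap A [wavelength_map()].
#' @param mode `"radiance"` or `"irradiance"`.
#' @param sigma Gaussian smoothing width in photosites.
#' @return An object of class `sensitivity_curve` with fields `mode` and
#'   per-photosite `S` (peak-normalised).
#' @export
derive_sensitivity <- function(measured, reference, wmap,
                               mode = c("radiance", "irradiance"), sigma = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(measured, "count_spectrum"),
            inherits(reference, "scene_spectrum"),
            inherits(wmap, "wavelength_map"))
  ref_p <- scene_value_at(reference, wmap$lambda)
  if (any(ref_p <= 1e-9 * max(ref_p))) {
    stop("reference spectrum must be strictly positive across the instrument band")
  }
  s <- (measured$c / measured$integration_ms / wmap$B) / ref_p
  s <- gaussian_smooth(s, sigma)
  sensitivity_curve(mode, s / max(s))
}

#' @rdname derive_sensitivity
#' @param S Per-photosite sensitivity values.
#' @export
sensitivity_curve <- function(mode = c("radiance", "irradiance"), S) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(S), all(is.finite(S)))
  structure(list(mode = mode, S = as.numeric(S)), class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> %s, %d photosites, peak %.4g\n",
              x$mode, length(x$S), max(x$S)))
  invisible(x)
}

#' Absolute radiometric scaling of a relative sensitivity curve
#'
#' Transfers absolute units onto a relative sensitivity curve using a
#' measurement of a standard source of known absolute spectrum (on the
#' bench, an AMOLED screen measured simultaneously with a
#' NIST-traceable reference instrument). A single scalar `k` is chosen
#' by least squares so that converting the measured counts with `k * S`
#' reproduces the standard's absolute values; since calibrated values
#' scale as 1/S, `k = sum(pred^2) / sum(pred * truth)` where `pred` is
#' the spectrum predicted with the relative curve.
#'
#' @param relative A relative [sensitivity_curve()].
#' @param measured_of_standard A linearised [count_spectrum()] of the
#'   standard source.
#' @param standard_truth A [scene_spectrum()]: the standard's known
#'   absolute spectrum.
#' @param wmap A [wavelength_map()].
#' @param s_floor Fraction of the peak sensitivity below which photosites
#'   are excluded from the least-squares scale (insensitive spectral ends).
#' @return An absolute [sensitivity_curve()] (`k * S`).
#' @export
absolute_scale <- function(relative, measured_of_standard, standard_truth,
                           wmap, s_floor = 0.02) {
  stopifnot(inherits(relative, "sensitivity_curve"),
            inherits(measured_of_standard, "count_spectrum"),
            inherits(standard_truth, "scene_spectrum"),
            relative$mode == standard_truth$mode)
  truth_p <- scene_value_at(standard_truth, wmap$lambda)
  if (all(truth_p == 0)) stop("standard spectrum is identically zero")
  use <- relative$S > s_floor * max(relative$S) & truth_p > 0
  if (!any(use)) stop("no photosites usable for absolute scaling")
  pred <- measured_of_standard$c /
    (relative$S * measured_of_standard$integration_ms * wmap$B)
  k <- sum(pred[use]^2) / sum(pred[use] * truth_p[use])
  sensitivity_curve(relative$mode, k * relative$S)
}

#' Cosine-corrector angular-response evaluation
#'
#' An ideal cosine corrector scatters transmitted light so that its
#' signal follows cos(theta) of the incidence angle. Given one scalar
#' reading per angle, returns the reading normalised to normal incidence
#' and its deviation from the ideal cosine (1 = Lambertian).
#'
#' @param angles_deg Incidence angles in degrees, each in `[0, 90)`,
#'   including 0.
#' @param readings One positive reading per angle (any consistent unit).
#' @return A data frame with columns `angle_deg`, `normalised`
#'   (`reading / reading(0)`) and `deviation` (`normalised / cos(theta)`).
#' @export
#' @examples
#' th <- seq(0, 80, by = 10)
#' cosine_deviation(th, cos(th * pi / 180))$deviation  # all 1
cosine_deviation <- function(angles_deg, readings) {
  stopifnot(length(angles_deg) == length(readings))
  if (any(angles_deg < 0 | angles_deg >= 90)) {
    stop("angles must lie in [0, 90) degrees")
  }
  i0 <- which(angles_deg == 0)
  if (length(i0) == 0L) stop("a reading at 0 degrees is required")
  r0 <- mean(readings[i0])
  if (r0 <= 0) stop("the normal-incidence reading must be positive")
  normalised <- readings / r0
  data.frame(angle_deg = angles_deg,
             normalised = normalised,
             deviation = normalised / cos(angles_deg * pi / 180))
}
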