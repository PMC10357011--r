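#' Scan-count rule: how many exposures to average
#'
#' The controller averages up to 50 exposures per measurement. When 50
#' exposures would take longer than 1 s in total, the number of averaged
#' exposures is reduced so the measurement stays strictly under 1 s,
#' down to a minimum of three exposures.
#'
#' @param integration_ms Integration time per exposure, ms (> 0).
#' @return An integer in `[3, 50]`.
#' @export
#' @examples
#' choose_scan_count(1)      # 50
#' choose_scan_count(100)    # 9
#' choose_scan_count(30000)  # 3
choose_scan_count <- function(integration_ms) {
  stopifnot(length(integration_ms) == 1L, is.finite(integration_ms))
  if (integration_ms <= 0) stop("integration time must be positive")
  q <- 1000 / integration_ms
  n <- if (abs(q - round(q)) < 1e-9) round(q) - 1 else floor(q)
  as.integer(max(3, min(50, n)))
}

#' Exposure plan
#'
#' @param integration_ms Integration time per exposure, ms.
#' @param n_scans Number of exposures to average, in `[3, 50]`.
#' @param saturated_at_minimum `TRUE` when even the minimum integration
#'   time saturates the sensor (the measurement will underestimate flux).
#' @param config A [sensor_config()] for range validation.
#' @return An object of class `exposure_plan`. Dark frames are interleaved
#'   with light frames whenever the integration time exceeds 1 s.
#' @export
exposure_plan <- function(integration_ms, n_scans = choose_scan_count(integration_ms),
                          saturated_at_minimum = FALSE,
                          config = sensor_config()) {
  stopifnot(n_scans >= 3L, n_scans <= 50L,
            integration_ms >= config$min_integration_ms,
            integration_ms <= config$max_integration_ms)
  structure(list(integration_ms = integration_ms,
                 n_scans = as.integer(n_scans),
                 interleave_dark = integration_ms > 1000,
                 saturated_at_minimum = isTRUE(saturated_at_minimum)),
            class = "exposure_plan")
}

#' @export
print.exposure_plan <- function(x, ...) {
  cat(sprintf("<exposure_plan> %g ms x %d scans%s%s\n",
              x$integration_ms, x$n_scans,
              if (x$interleave_dark) ", interleaved darks" else "",
              if (x$saturated_at_minimum) ", SATURATED at minimum" else ""))
  invisible(x)
}

#' Automatic integration-time selection
#'
#' Emulates the controller's auto-exposure: starting from the minimum
#' integration time, test exposures are taken with the integration time
#' doubling until any photosite reaches the saturation ceiling (or the
#' 30 s maximum is reached). The preceding unsaturated exposure is then
#' used to compute the integration time that would put the peak intensity
#' at 0.8 of saturation:
#' `t = t_last * 0.8 * usable_levels / peak_dark_free(t_last)`,
#' clamped to the permitted range. Saturation is detected on the raw
#' light counts (it cannot be judged after dark subtraction), while the
#' 0.8 targeting uses counts above the dark mean estimate. A source that
#' saturates even the minimum exposure yields the minimum integration
#' time with `saturated_at_minimum = TRUE`; a source too dim for the
#' target yields the 30 s maximum.
#'
#' @param measure_fn Function of one argument (integration time in ms)
#'   returning a `raw_frame`, e.g. a closure over [simulate_frame()].
#' @param config A [sensor_config()].
#' @return An [exposure_plan()].
#' @export
#' @examples
#' cfg <- sensor_config(dark_sd = 0, read_noise_sd = 0, shot_noise = FALSE)
#' sc <- scene_flat(0.01)
#' plan <- auto_expose(function(t) simulate_frame(sc, t, "radiance", cfg), cfg)
auto_expose <- function(measure_fn, config = sensor_config()) {
  stopifnot(is.function(measure_fn), inherits(config, "sensor_config"))
  ceiling_cts <- config$usable_levels
  t <- config$min_integration_ms
  t_prev <- NA_real_
  peak_prev <- NA_real_
  repeat {
    frame <- measure_fn(t)
    if (!inherits(frame, "raw_frame")) {
      stop("auto_expose: measure_fn must return a raw_frame (got ",
           class(frame)[1], ")")
    }
    saturated <- any(frame$counts >= ceiling_cts)
    if (saturated) {
      if (is.na(t_prev)) {
        return(exposure_plan(config$min_integration_ms,
                             saturated_at_minimum = TRUE, config = config))
      }
      break
    }
    t_prev <- t
    peak_prev <- max(frame$counts - config$dark_mean)
    if (t >= config$max_integration_ms) break
    t <- min(t * 2, config$max_integration_ms)
  }
  if (peak_prev <= 0) {
    target <- config$max_integration_ms
  } else {
    target <- t_prev * 0.8 * ceiling_cts / peak_prev
  }
  target <- min(max(target, config$min_integration_ms), config$max_integration_ms)
  exposure_plan(target, config = config)
}

#' Dark-subtracted count spectrum
#'
#' @param c Per-photosite dark-subtracted counts (may be negative).
#' @param integration_ms Integration time per exposure, ms.
#' @param n_scans Number of exposures averaged.
#' @param n_saturated Number of photosites whose raw light counts reached
#'   the saturation ceiling in any scan.
#' @return An object of class `count_spectrum`.
#' @export
count_spectrum <- function(c, integration_ms, n_scans, n_saturated = 0L) {
  stopifnot(is.numeric(c), integration_ms > 0, n_scans >= 1L,
            n_saturated >= 0L, n_saturated <= length(c))
  structure(list(c = as.numeric(c), integration_ms = integration_ms,
                 n_scans = as.integer(n_scans),
                 n_saturated = as.integer(n_saturated)),
            class = "count_spectrum")
}

#' @export
print.count_spectrum <- function(x, ...) {
  cat(sprintf("<count_spectrum> %d photosites, %g ms x %d scans, %d saturated\n",
              length(x$c), x$integration_ms, x$n_scans, x$n_saturated))
  invisible(x)
}

#' Acquire a dark-subtracted, scan-averaged measurement
#'
#' Takes `n_scans` light frames and `n_scans` shutter-closed dark frames
#' with an identical exposure regime, strictly alternating light and dark
#' frames when the integration time exceeds 1 s (closer temporal matching
#' of the black point for long exposures) and taking the light block
#' before the dark block otherwise. The dark-subtracted counts are
#' `c_p = mean(l_p) - mean(d_p)`, which controls for temperature and
#' voltage fluctuations of the sensor's black point. Saturated photosites
#' are counted on the raw light frames before subtraction.
#'
#' @param scene A [scene_spectrum()].
#' @param plan An [exposure_plan()].
#' @param config A [sensor_config()].
#' @param seed Optional integer seed for the whole acquisition.
#' @return A [count_spectrum()].
#' @export
acquire <- function(scene, plan, config = sensor_config(), seed = NULL) {
  stopifnot(inherits(scene, "scene_spectrum"), inherits(plan, "exposure_plan"))
  if (!is.null(seed)) set.seed(seed)
  config$rng_seed <- NULL  # frames must draw from the acquisition stream
  n <- plan$n_scans
  shutter <- scene$mode
  light <- matrix(0, config$n_photosites, n)
  dark <- matrix(0, config$n_photosites, n)
  if (plan$interleave_dark) {
    for (i in seq_len(n)) {
      light[, i] <- simulate_frame(scene, plan$integration_ms, shutter, config)$counts
      dark[, i] <- simulate_frame(NULL, plan$integration_ms, "closed", config)$counts
    }
  } else {
    for (i in seq_len(n)) {
      light[, i] <- simulate_frame(scene, plan$integration_ms, shutter, config)$counts
    }
    for (i in seq_len(n)) {
      dark[, i] <- simulate_frame(NULL, plan$integration_ms, "closed", config)$counts
    }
  }
  n_sat <- sum(apply(light >= config$usable_levels, 1, any))
  count_spectrum(rowMeans(light) - rowMeans(dark),
                 plan$integration_ms, n, n_sat)
}
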