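#' Per-unit calibration record
#'
#' Bundles everything needed to calibrate a unit's measurements: the
#' wavelength polynomial, the two linearisation coefficients and the
#' radiance/irradiance sensitivity curves. Records are persisted in
#' `calibration_data.csv`, one row per unit, and looked up by unit
#' identifier at processing time.
#'
#' @param unit_id Unit identifier, unique within a calibration file.
#' @param wavelength_coeffs Up to 6 polynomial coefficients (zero-padded).
#' @param lin_a,lin_b Linearisation coefficients (see [lin_model()]).
#' @param S_r,S_i Per-photosite radiance and irradiance sensitivities,
#'   counts ms^-1 per (spectral-flux unit) nm.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(unit_id, wavelength_coeffs, lin_a, lin_b, S_r, S_i) {
  stopifnot(length(S_r) == length(S_i), lin_a > 0, lin_b > 0)
  structure(list(unit_id = as.character(unit_id),
                 wavelength_coeffs = pad_coeffs(wavelength_coeffs),
                 lin_a = lin_a, lin_b = lin_b,
                 S_r = as.numeric(S_r), S_i = as.numeric(S_i)),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> unit %s: a = %.5g, b = %.5g, %d photosites\n",
              x$unit_id, x$lin_a, x$lin_b, length(x$S_r)))
  invisible(x)
}

#' Calibration record matching a simulated unit's ground truth
#'
#' Builds the calibration record that exactly matches a simulator
#' configuration (same wavelength polynomial, nonlinearity coefficients
#' and sensitivity for both modes), so that processing simulated
#' acquisitions with it recovers the true scene. This is the oracle
#' calibration used throughout the round-trip tests.
#'
#' @param config A [sensor_config()].
#' @param unit_id Identifier for the simulated unit.
#' @return A [calibration_record()].
#' @export
default_calibration <- function(config = sensor_config(), unit_id = "SIM") {
  stopifnot(inherits(config, "sensor_config"))
  calibration_record(unit_id, config$wavelength_coeffs,
                     config$nonlin_a, config$nonlin_b,
                     config$true_sensitivity, config$true_sensitivity)
}

fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

calibration_header <- function(n) {
  c("unit_id", paste0("wl_c", 0:5), "lin_a", "lin_b",
    paste0("Sr_", seq_len(n) - 1), paste0("Si_", seq_len(n) - 1))
}

#' Read and write `calibration_data.csv`
#'
#' Plain CSV (comma separator, '.' decimal, header row, UTF-8), one row
#' per unit: `unit_id`, wavelength polynomial coefficients `wl_c0..wl_c5`,
#' linearisation coefficients `lin_a`, `lin_b`, then per-photosite wide
#' blocks `Sr_0..` and `Si_0..`. Numeric fields are serialised with 17
#' significant digits so the round trip is bit-exact. Unknown extra
#' columns are preserved on read (attached as an attribute) and a
#' missing required column or duplicate unit identifier is rejected.
#'
#' @param records A list of [calibration_record()]s (or a single one).
#' @param path File path (conventionally `calibration_data.csv`).
#' @return `read_calibration()` returns a named list of
#'   `calibration_record`s keyed by `unit_id`; `write_calibration()`
#'   returns `path` invisibly.
#' @export
write_calibration <- function(records, path) {
  if (inherits(records, "calibration_record")) records <- list(records)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "calibration_record")))
  ids <- vapply(records, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit_id in calibration records")
  n <- length(records[[1]]$S_r)
  lines <- vapply(records, function(r) {
    stopifnot(length(r$S_r) == n)
    paste(c(r$unit_id, fmt_num(r$wavelength_coeffs), fmt_num(r$lin_a),
            fmt_num(r$lin_b), fmt_num(r$S_r), fmt_num(r$S_i)),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(calibration_header(n), collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  n <- sum(grepl("^Sr_", names(df)))
  required <- calibration_header(n)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("calibration file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$unit_id)) {
    stop("duplicate unit_id in calibration file: ",
         paste(unique(df$unit_id[duplicated(df$unit_id)]), collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    calibration_record(
      row$unit_id,
      as.numeric(unlist(row[paste0("wl_c", 0:5)])),
      as.numeric(row$lin_a), as.numeric(row$lin_b),
      as.numeric(unlist(row[paste0("Sr_", seq_len(n) - 1)])),
      as.numeric(unlist(row[paste0("Si_", seq_len(n) - 1)])))
  })
  names(records) <- df$unit_id
  if (length(extra)) attr(records, "extra_columns") <- df[, extra, drop = FALSE]
  records
}

measurement_header <- function(n) {
  c("unit_id", "label", "timestamp", "mode", "integration_ms", "n_scans",
    "n_saturated", paste0("wl_", seq_len(n) - 1),
    paste0("val_", seq_len(n) - 1), paste0("raw_", seq_len(n) - 1))
}

measurement_row <- function(record) {
  paste(c(record$unit_id, record$label, record$timestamp, record$mode,
          fmt_num(record$integration_ms), record$n_scans, record$n_saturated,
          fmt_num(record$lambda), fmt_num(record$values),
          fmt_num(record$raw_counts)),
        collapse = ",")
}

#' Append a measurement to `data.csv`
#'
#' Measurements are appended without rewriting prior rows, so the data
#' file is an audit trail. The schema mirrors the displayed measurement:
#' unit identifier, label, timestamp, mode, integration time, scan
#' count, saturated-photosite count, then wide per-photosite blocks of
#' wavelength, calibrated value and raw count. Appending the same record
#' twice in a row is rejected (the re-save guard: a new measurement must
#' be taken first), as is appending to a file with a different schema.
#'
#' @param record A [calibrated_spectrum()].
#' @param path File path (conventionally `data.csv`).
#' @return `path`, invisibly.
#' @export
append_measurement <- function(record, path) {
  stopifnot(inherits(record, "calibrated_spectrum"))
  n <- length(record$values)
  header <- paste(measurement_header(n), collapse = ",")
  row <- measurement_row(record)
  if (file.exists(path) && file.size(path) > 0) {
    lines <- readLines(path)
    if (lines[1] != header) {
      stop("existing measurement file has a different schema: ", path)
    }
    if (lines[length(lines)] == row) {
      stop("refusing to re-save: identical to the last saved measurement")
    }
    cat(row, "\n", sep = "", file = path, append = TRUE)
  } else {
    writeLines(c(header, row), path)
  }
  invisible(path)
}

#' Read measurements back from `data.csv`
#'
#' @param path File path.
#' @return A list of [calibrated_spectrum()] objects; numeric fields
#'   round-trip bit-exactly.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  n <- sum(grepl("^wl_", names(df)))
  missing <- setdiff(measurement_header(n), names(df))
  if (length(missing)) {
    stop("measurement file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    calibrated_spectrum(
      row$unit_id, row$label, row$timestamp, row$mode,
      as.numeric(unlist(row[paste0("wl_", seq_len(n) - 1)])),
      as.numeric(unlist(row[paste0("val_", seq_len(n) - 1)])),
      as.numeric(row$integration_ms), as.integer(row$n_scans),
      as.integer(row$n_saturated),
      as.numeric(row[paste0("raw_", seq_len(n) - 1)]))
  })
}

#' Re-calibrate a stored measurement from its raw counts
#'
#' Because raw count data are stored uncalibrated alongside every
#' measurement, any measurement can be re-calibrated after recording —
#' for instance once a unit is properly calibrated, or to apply a
#' low-light dark-offset correction. Calibrated values are recomputed
#' from the stored raw counts, integration time and the new calibration;
#' label, timestamp and mode are preserved.
#'
#' @param record A [calibrated_spectrum()] with raw counts present.
#' @param new_calib A [calibration_record()].
#' @param dark_offset Optional fixed dark offset (counts) subtracted from
#'   the raw counts before conversion; `NULL` applies none.
#' @return A [calibrated_spectrum()] with replaced values (and the new
#'   calibration's unit identifier).
#' @export
recalibrate <- function(record, new_calib, dark_offset = NULL) {
  stopifnot(inherits(record, "calibrated_spectrum"),
            inherits(new_calib, "calibration_record"))
  if (is.null(record$raw_counts) || !length(record$raw_counts)) {
    stop("cannot re-calibrate: raw counts are missing from the record")
  }
  cs <- count_spectrum(record$raw_counts, record$integration_ms,
                       record$n_scans, record$n_saturated)
  if (!is.null(dark_offset)) {
    cs <- dark_offset_correct(cs, record$mode, offset = dark_offset)
  }
  out <- counts_to_spectrum(cs, new_calib, record$mode,
                            label = record$label, timestamp = record$timestamp)
  out$raw_counts <- record$raw_counts  # keep the original, pre-offset counts
  out
}
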