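#' Exposure design of a dosimetry protocol
#'
#' @param n_exposures number of exposures accumulated per protocol (>= 1).
#' @param exposure_s duration of one accumulated exposure, seconds (> 0).
#' @param single_exposure_s duration of the single clinical exposure that
#'   the reported effective dose refers to, seconds (> 0).
#' @return A list of class `exposure_design`.
#' @export
exposure_design <- function(n_exposures = 50, exposure_s = 5,
                            single_exposure_s = 0.6) {
  n_exposures <- as.numeric(n_exposures)
  if (is.na(n_exposures) || n_exposures < 1)
    stop("'n_exposures' must be >= 1")
  if (!is.numeric(exposure_s) || exposure_s <= 0 ||
      !is.numeric(single_exposure_s) || single_exposure_s <= 0)
    stop("exposure durations must be positive")
  structure(list(n_exposures = n_exposures, exposure_s = exposure_s,
                 single_exposure_s = single_exposure_s),
            class = "exposure_design")
}

#' Container for all raw read-outs of a dosimetry experiment
#'
#' Bundles the three read-out tables (exposed dosimeters, calibration
#' dosimeters, unexposed background dosimeters) with the exposure design.
#' All read-outs are in pulse counts from the read-out oven.
#'
#' @param readings data frame with columns `protocol`, `location`,
#'   `position` (dosimeter index within the location) and `pulses`.
#' @param calibration data frame with columns `dosimeter_id` and `pulses`.
#' @param background data frame with columns `protocol`, `dosimeter_id`
#'   and `pulses`; every protocol present in `readings` needs at least one
#'   background reading.
#' @param known_dose dose delivered to the calibration dosimeters, mGy (> 0).
#' @param design an [exposure_design()].
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(readings, calibration, background, known_dose,
                            design = exposure_design()) {
  readings <- as.data.frame(readings)
  calibration <- as.data.frame(calibration)
  background <- as.data.frame(background)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  need(readings, c("protocol", "location", "position", "pulses"), "'readings'")
  need(calibration, c("dosimeter_id", "pulses"), "'calibration'")
  need(background, c("protocol", "dosimeter_id", "pulses"), "'background'")
  if (any(readings$pulses < 0) || any(calibration$pulses < 0) ||
      any(background$pulses < 0))
    stop("pulse counts must be non-negative")
  if (!is.numeric(known_dose) || known_dose <= 0)
    stop("'known_dose' must be a positive dose in mGy")
  if (!inherits(design, "exposure_design"))
    design <- do.call(exposure_design, as.list(design))

  protocols <- unique(as.character(readings$protocol))
  no_bg <- setdiff(protocols, unique(as.character(background$protocol)))
  if (length(no_bg))
    stop("no background readings for protocol(s): ",
         paste(no_bg, collapse = ", "))

  structure(
    list(readings = readings, calibration = calibration,
         background = background, known_dose = known_dose,
         design = design, protocols = protocols),
    class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  k <- stats::aggregate(position ~ protocol + location, x$readings, length)$position
  cat("Dosimetry measurement set\n")
  cat("  protocols:   ", paste(x$protocols, collapse = ", "), "\n")
  cat("  locations:   ", length(unique(x$readings$location)),
      sprintf(" (%s dosimeters/location)",
              if (length(unique(k)) == 1L) unique(k) else "1-varying"), "\n")
  cat("  calibration: ", nrow(x$calibration), "dosimeters at",
      x$known_dose, "mGy\n")
  cat("  background:  ", nrow(x$background), "readings\n")
  cat(sprintf("  design:       %g exposures x %g s (single exposure %g s)\n",
              x$design$n_exposures, x$design$exposure_s,
              x$design$single_exposure_s))
  invisible(x)
}

#' Check a measurement set against a phantom layout
#'
#' Verifies that every layout location has at least one reading in every
#' protocol, the precondition for the dose calculation chain.
#'
#' @param measurements a [measurement_set()].
#' @param layout a [phantom_layout()].
#' @return Invisibly `TRUE`; otherwise an error naming the missing
#'   protocol/location pairs.
#' @export
validate_measurements <- function(measurements, layout) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(layout, "phantom_layout"))
  r <- measurements$readings
  for (p in measurements$protocols) {
    have <- unique(as.character(r$location[r$protocol == p]))
    miss <- setdiff(layout$locations, have)
    if (length(miss))
      stop("protocol '", p, "' has no readings for location(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a measurement set from CSV files
#'
#' File dialects (UTF-8, comma-separated, header required):
#' \itemize{
#'   \item measurements: `protocol,location,position,pulses`
#'   \item calibration: `dosimeter_id,pulses`
#'   \item background: `protocol,dosimeter_id,pulses`
#' }
#'
#' @param measurements_csv,calibration_csv,background_csv file paths.
#' @param known_dose calibration dose in mGy (usually from the layout
#'   config, see [read_layout_config()]).
#' @param design an [exposure_design()].
#' @return A [measurement_set()].
#' @export
read_measurement_set <- function(measurements_csv, calibration_csv,
                                 background_csv, known_dose,
                                 design = exposure_design()) {
  measurement_set(
    readings = utils::read.csv(measurements_csv),
    calibration = utils::read.csv(calibration_csv),
    background = utils::read.csv(background_csv),
    known_dose = known_dose, design = design)
}

#' Write a measurement set to CSV files
#'
#' Writes `measurements.csv`, `calibration.csv` and `background.csv` in the
#' dialects read by [read_measurement_set()].
#'
#' @param measurements a [measurement_set()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_measurement_set <- function(measurements, dir) {
  stopifnot(inherits(measurements, "measurement_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "calibration.csv",
                            "background.csv"))
  utils::write.csv(measurements$readings, paths[1], row.names = FALSE)
  utils::write.csv(measurements$calibration, paths[2], row.names = FALSE)
  utils::write.csv(measurements$background, paths[3], row.names = FALSE)
  invisible(paths)
}
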