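#' Calibration factor from calibration read-outs
#'
#' The calibration factor (CF) converts oven pulse counts to absorbed dose.
#' The mean CF is the average calibration read-out divided by the known
#' delivered dose; the spread of the per-dosimeter CFs is the empirical
#' estimate of the calibration component of random error.
#'
#' @param calibration either a numeric vector of pulse counts or a data
#'   frame with a `pulses` column (as in [measurement_set()]).
#' @param known_dose the dose delivered to the calibration dosimeters, mGy.
#' @return An object of class `calibration_summary` with fields `mean_cf`
#'   (pulses/mGy), `per_dosimeter_cf`, `cf_rsd_percent` (sample RSD, \%)
#'   and `n`.
#' @examples
#' compute_calibration(c(900, 1100), known_dose = 10)
#' @export
compute_calibration <- function(calibration, known_dose) {
  pulses <- if (is.data.frame(calibration)) calibration$pulses
            else as.numeric(calibration)
  if (length(pulses) < 2L)
    stop("at least 2 calibration readings are required")
  if (!is.numeric(known_dose) || known_dose <= 0)
    stop("'known_dose' must be positive")
  if (any(pulses <= 0))
    stop("calibration pulse counts must be positive")
  cf <- pulses / known_dose
  structure(
    list(mean_cf = mean(cf), per_dosimeter_cf = cf,
         cf_rsd_percent = 100 * stats::sd(cf) / mean(cf),
         n = length(cf)),
    class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf(
    "Calibration: mean CF = %.4g pulses/mGy (RSD %.2f%%, n = %d)\n",
    x$mean_cf, x$cf_rsd_percent, x$n))
  invisible(x)
}

#' Background radiation level from unexposed dosimeters
#'
#' @param pulses read-outs of the unexposed dosimeters of one protocol.
#' @param rsd_if_single value reported as the RSD when only one reading is
#'   available (a spread cannot be estimated): `0` (default) or `NA`.
#' @return List with `mean_bg_pulses` and `bg_rsd_percent` (sample RSD, \%).
#' @examples
#' compute_background(c(90, 100, 110))
#' @export
compute_background <- function(pulses, rsd_if_single = 0) {
  pulses <- as.numeric(pulses)
  if (length(pulses) < 1L)
    stop("at least 1 background reading is required")
  rsd <- if (length(pulses) >= 2L && mean(pulses) > 0)
    100 * stats::sd(pulses) / mean(pulses) else rsd_if_single
  list(mean_bg_pulses = mean(pulses), bg_rsd_percent = rsd)
}

#' Absorbed dose per phantom location for one protocol
#'
#' Dosimeter readings at each location are averaged, the mean background
#' is subtracted in pulse units, and the corrected value is divided by the
#' mean calibration factor. Corrected values below zero are physically
#' impossible and are clamped to 0 with a warning (set
#' `clamp_negative = FALSE` to keep them, e.g. for variance studies).
#'
#' @param readings data frame with `location` and `pulses` columns holding
#'   one protocol's exposed read-outs.
#' @param calibration a `calibration_summary` (or a bare mean CF in
#'   pulses/mGy).
#' @param mean_bg_pulses mean background level in pulses (>= 0).
#' @param locations locations that must be present; defaults to those in
#'   `readings`.
#' @param clamp_negative clamp negative corrected doses to 0 (default TRUE).
#' @return Named numeric vector: absorbed dose in mGy per location.
#' @export
compute_location_doses <- function(readings, calibration, mean_bg_pulses,
                                   locations = NULL, clamp_negative = TRUE) {
  mean_cf <- if (inherits(calibration, "calibration_summary"))
    calibration$mean_cf else as.numeric(calibration)
  if (mean_cf <= 0) stop("mean CF must be positive")
  if (mean_bg_pulses < 0) stop("'mean_bg_pulses' must be >= 0")
  if (is.null(locations)) locations <- unique(as.character(readings$location))
  miss <- setdiff(locations, as.character(readings$location))
  if (length(miss))
    stop("no readings for location(s): ", paste(miss, collapse = ", "))
  loc_mean <- tapply(readings$pulses, as.character(readings$location), mean)
  doses <- (loc_mean[locations] - mean_bg_pulses) / mean_cf
  names(doses) <- locations
  if (clamp_negative && any(doses < 0)) {
    warning(sum(doses < 0),
            " location dose(s) below background were clamped to 0")
    doses[doses < 0] <- 0
  }
  doses
}

#' Equivalent dose per tissue
#'
#' Each tissue's dose is the mean absorbed dose over its mapped locations
#' multiplied by the irradiated fraction of the tissue. For X-rays the
#' radiation weighting factor is 1, so absorbed dose (mGy) and equivalent
#' dose (mSv) coincide numerically.
#'
#' @param location_doses named numeric vector from
#'   [compute_location_doses()].
#' @param layout a [phantom_layout()].
#' @return Named numeric vector: equivalent dose per tissue.
#' @export
compute_tissue_doses <- function(location_doses, layout) {
  stopifnot(inherits(layout, "phantom_layout"))
  vapply(layout$tissues, function(t) {
    miss <- setdiff(t$locations, names(location_doses))
    if (length(miss))
      stop("tissue dose needs missing location(s): ",
           paste(miss, collapse = ", "))
    t$fraction * mean(location_doses[t$locations])
  }, numeric(1))
}

#' Effective dose from tissue doses
#'
#' The ICRP risk-weighted summation `E = sum_T w_T * D_T`, multiplied by
#' the layout's unit-conversion constant (e.g. 1000 to report microsievert
#' for tissue doses in mGy).
#'
#' @param tissue_doses named numeric vector from [compute_tissue_doses()].
#' @param layout a [phantom_layout()]; every tissue in `tissue_doses` must
#'   carry a weighting factor.
#' @param convert apply the layout's `dose_to_uSv` constant (default TRUE).
#' @return Effective dose (scalar).
#' @export
compute_effective_dose <- function(tissue_doses, layout, convert = TRUE) {
  stopifnot(inherits(layout, "phantom_layout"))
  miss <- setdiff(names(tissue_doses), names(layout$tissues))
  if (length(miss))
    stop("no weighting factor for tissue(s): ", paste(miss, collapse = ", "))
  w <- vapply(layout$tissues[names(tissue_doses)], `[[`, numeric(1), "weight")
  e <- sum(w * tissue_doses)
  if (convert) e * layout$dose_to_uSv else e
}

#' Protocol-to-single-exposure conversion ratio
#'
#' A protocol accumulates `n_exposures` exposures of `exposure_s` seconds;
#' the reported effective dose refers to one clinical exposure of
#' `single_exposure_s` seconds. The protocol dose is divided by this ratio
#' of total to single exposure time.
#'
#' @param design an [exposure_design()].
#' @return Dimensionless ratio (e.g. 50 x 5 s / 0.6 s = 416.67).
#' @examples
#' single_exposure_ratio(exposure_design(50, 5, 0.6))
#' @export
single_exposure_ratio <- function(design) {
  if (!inherits(design, "exposure_design"))
    design <- do.call(exposure_design, as.list(design))
  design$n_exposures * design$exposure_s / design$single_exposure_s
}

#' Deterministic effective dose per single exposure for one protocol
#'
#' Composes the full calculation chain without any error perturbation:
#' calibration, background correction, location doses, tissue doses,
#' weighted summation and conversion to a single exposure.
#'
#' @param measurements a [measurement_set()].
#' @param layout a [phantom_layout()].
#' @param protocol protocol identifier present in the measurement set.
#' @param clamp_negative see [compute_location_doses()].
#' @return Effective dose per single exposure (in the layout's report
#'   unit, microsievert with the default conversion).
#' @export
compute_protocol_E <- function(measurements, layout, protocol,
                               clamp_negative = TRUE) {
  stopifnot(inherits(measurements, "measurement_set"))
  if (!protocol %in% measurements$protocols)
    stop("unknown protocol: ", protocol)
  cal <- compute_calibration(measurements$calibration,
                             measurements$known_dose)
  bgp <- measurements$background$pulses[
    measurements$background$protocol == protocol]
  bg <- compute_background(bgp)
  rd <- measurements$readings[measurements$readings$protocol == protocol, ]
  ld <- compute_location_doses(rd, cal, bg$mean_bg_pulses,
                               locations = layout$locations,
                               clamp_negative = clamp_negative)
  td <- compute_tissue_doses(ld, layout)
  compute_effective_dose(td, layout) / single_exposure_ratio(measurements$design)
}

#' Deterministic effective dose per single exposure, all protocols
#'
#' @inheritParams compute_protocol_E
#' @return Named numeric vector, one effective dose per protocol.
#' @export
effective_dose <- function(measurements, layout, clamp_negative = TRUE) {
  validate_measurements(measurements, layout)
  vapply(measurements$protocols, function(p)
    compute_protocol_E(measurements, layout, p, clamp_negative),
    numeric(1))
}
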