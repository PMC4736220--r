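#' Phantom layout: locations, tissue mapping and tissue weighting factors
#'
#' A `phantom_layout` describes the geometry-to-risk mapping of a dosimetry
#' phantom: the dosimeter locations, which locations contribute to which
#' tissue, the fraction of each tissue that lies in the irradiated volume,
#' and the ICRP tissue weighting factors used in the effective-dose
#' summation.
#'
#' @param locations character vector of location identifiers.
#' @param tissues named list; each element is a list with components
#'   `weight` (dimensionless ICRP tissue weighting factor, >= 0),
#'   `locations` (character vector of location ids, non-empty) and
#'   `fraction` (irradiated fraction of the tissue, in `[0, 1]`).
#'   A location may feed several tissues.
#' @param dose_to_uSv unit-conversion constant applied to the weighted
#'   tissue-dose sum. With tissue doses in mGy (and a radiation weighting
#'   factor of 1 for X-rays, so mGy is numerically mSv), `1000` reports the
#'   effective dose in microsievert. Use `1` to keep the raw weighted sum.
#' @param check_weights how to treat the sum of the supplied weighting
#'   factors: `"partial"` (default) accepts a head/neck subset of the full
#'   ICRP table and records that the table is partial; `"full"` requires the
#'   weights to sum to 1 (within 1e-6) as the complete ICRP table does.
#'
#' @return An object of class `phantom_layout`.
#' @seealso [default_layout()], [icrp103_weights()], [compute_effective_dose()]
#' @export
phantom_layout <- function(locations, tissues, dose_to_uSv = 1,
                           check_weights = c("partial", "full")) {
  check_weights <- match.arg(check_weights)
  locations <- as.character(locations)
  if (length(locations) < 1L || anyDuplicated(locations))
    stop("'locations' must be a non-empty set of unique identifiers")
  if (!is.list(tissues) || is.null(names(tissues)) || any(names(tissues) == ""))
    stop("'tissues' must be a named list")

  for (tn in names(tissues)) {
    t <- tissues[[tn]]
    if (is.null(t$weight) || t$weight < 0)
      stop("tissue '", tn, "': weighting factor must be >= 0")
    if (is.null(t$locations) || length(t$locations) == 0L)
      stop("tissue '", tn, "' is mapped to zero locations")
    missing <- setdiff(t$locations, locations)
    if (length(missing))
      stop("tissue '", tn, "' references unknown location(s): ",
           paste(missing, collapse = ", "))
    if (is.null(t$fraction) || t$fraction < 0 || t$fraction > 1)
      stop("tissue '", tn, "': irradiated fraction must be in [0, 1]")
  }

  wsum <- sum(vapply(tissues, function(t) t$weight, numeric(1)))
  full_table <- abs(wsum - 1) < 1e-6
  if (check_weights == "full" && !full_table)
    stop("tissue weighting factors sum to ", signif(wsum, 4),
         ", not 1; a full ICRP table is required (check_weights = \"full\")")

  structure(
    list(locations = locations, tissues = tissues,
         dose_to_uSv = dose_to_uSv,
         weight_sum = wsum, full_weight_table = full_table),
    class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("Phantom layout:", length(x$locations), "locations,",
      length(x$tissues), "tissues\n")
  cat(sprintf("  weighting factors sum to %.4g (%s table)\n", x$weight_sum,
              if (x$full_weight_table) "full ICRP" else "partial"))
  cat(sprintf("  dose-to-report conversion: x%g\n", x$dose_to_uSv))
  invisible(x)
}

#' Full ICRP Publication 103 tissue weighting factors
#'
#' The complete weighting-factor table (sums to 1). `remainder` is the
#' ICRP remainder group treated as a single entry.
#'
#' @return Named numeric vector of weighting factors.
#' @export
icrp103_weights <- function() {
  c(bone_marrow = 0.12, colon = 0.12, lung = 0.12, stomach = 0.12,
    breast = 0.12, remainder = 0.12, gonads = 0.08,
    bladder = 0.04, oesophagus = 0.04, liver = 0.04, thyroid = 0.04,
    bone_surface = 0.01, brain = 0.01, salivary_glands = 0.01, skin = 0.01)
}

#' Illustrative head/neck phantom layout
#'
#' A 25-location head phantom layout with an illustrative mapping of
#' locations to the head/neck tissues of the ICRP 103 table. The weighting
#' factors are the ICRP values; the location-to-tissue assignment and the
#' irradiated fractions are plausible values for a cephalometric exposure
#' of an anthropomorphic head phantom, supplied as a worked default --
#' real studies must substitute their own phantom's mapping.
#'
#' Locations may feed several tissues (e.g. mandible sites contribute to
#' both bone marrow and bone surface), which is what makes analytic error
#' propagation awkward and motivates the Monte Carlo approach.
#'
#' @param dose_to_uSv unit conversion, see [phantom_layout()]; default 1000
#'   reports effective dose in microsievert for tissue doses in mGy.
#' @return A `phantom_layout`.
#' @export
default_layout <- function(dose_to_uSv = 1000) {
  locations <- c(
    "calvarium_ant", "calvarium_left", "calvarium_post",
    "cervical_spine", "mandible_body_l", "mandible_body_r",
    "ramus_l", "ramus_r", "pituitary", "orbit_l", "orbit_r",
    "lens_l", "lens_r", "parotid_l", "parotid_r",
    "submandibular_l", "submandibular_r", "sublingual",
    "thyroid_l", "thyroid_r", "oesophagus_up",
    "skin_forehead", "skin_cheek_l", "skin_cheek_r", "back_of_neck")
  w <- icrp103_weights()
  tissues <- list(
    bone_marrow = list(
      weight = w[["bone_marrow"]], fraction = 0.165,
      locations = c("calvarium_ant", "calvarium_left", "calvarium_post",
                    "cervical_spine", "mandible_body_l", "mandible_body_r",
                    "ramus_l", "ramus_r")),
    bone_surface = list(
      weight = w[["bone_surface"]], fraction = 0.169,
      locations = c("calvarium_ant", "calvarium_left", "calvarium_post",
                    "cervical_spine", "mandible_body_l", "mandible_body_r",
                    "ramus_l", "ramus_r")),
    brain = list(
      weight = w[["brain"]], fraction = 1,
      locations = c("calvarium_ant", "calvarium_left", "calvarium_post",
                    "pituitary")),
    salivary_glands = list(
      weight = w[["salivary_glands"]], fraction = 1,
      locations = c("parotid_l", "parotid_r", "submandibular_l",
                    "submandibular_r", "sublingual")),
    thyroid = list(
      weight = w[["thyroid"]], fraction = 1,
      locations = c("thyroid_l", "thyroid_r")),
    oesophagus = list(
      weight = w[["oesophagus"]], fraction = 0.1,
      locations = "oesophagus_up"),
    skin = list(
      weight = w[["skin"]], fraction = 0.05,
      locations = c("skin_forehead", "skin_cheek_l", "skin_cheek_r",
                    "back_of_neck")),
    remainder = list(
      weight = w[["remainder"]], fraction = 0.12,
      locations = c("orbit_l", "orbit_r", "lens_l", "lens_r",
                    "sublingual", "oesophagus_up", "back_of_neck"))
  )
  phantom_layout(locations, tissues, dose_to_uSv = dose_to_uSv)
}

#' Read a layout / experiment configuration from YAML
#'
#' The configuration file holds everything that is configuration rather
#' than measurement: the phantom layout (locations, tissues with weight,
#' locations and irradiated fraction), the exposure design
#' (`n_exposures`, `exposure_s`, `single_exposure_s`), the calibration
#' `known_dose` in mGy, and the unit conversion `dose_to_uSv`.
#'
#' @param path path to a YAML file.
#' @return A list with components `layout` (a [phantom_layout()]),
#'   `design` (list with `n_exposures`, `exposure_s`, `single_exposure_s`)
#'   and `known_dose` (mGy; `NULL` if absent).
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$locations) || is.null(cfg$tissues))
    stop("layout config must contain 'locations' and 'tissues'")
  tissues <- lapply(cfg$tissues, function(t)
    list(weight = as.numeric(t$weight),
         locations = as.character(unlist(t$locations)),
         fraction = as.numeric(t$fraction)))
  layout <- phantom_layout(
    locations = as.character(unlist(cfg$locations)),
    tissues = tissues,
    dose_to_uSv = if (is.null(cfg$dose_to_uSv)) 1 else as.numeric(cfg$dose_to_uSv))
  design <- NULL
  if (!is.null(cfg$design))
    design <- exposure_design(n_exposures = cfg$design$n_exposures,
                              exposure_s = cfg$design$exposure_s,
                              single_exposure_s = cfg$design$single_exposure_s)
  list(layout = layout, design = design,
       known_dose = if (is.null(cfg$known_dose)) NULL else as.numeric(cfg$known_dose))
}

#' Write a layout / experiment configuration to YAML
#'
#' Inverse of [read_layout_config()].
#'
#' @param layout a [phantom_layout()].
#' @param path output file path.
#' @param design optional [exposure_design()].
#' @param known_dose optional calibration dose, mGy.
#' @return Invisibly, `path`.
#' @export
write_layout_config <- function(layout, path, design = NULL,
                                known_dose = NULL) {
  stopifnot(inherits(layout, "phantom_layout"))
  cfg <- list(
    locations = layout$locations,
    tissues = lapply(layout$tissues, function(t)
      list(weight = t$weight, fraction = t$fraction,
           locations = t$locations)),
    dose_to_uSv = layout$dose_to_uSv)
  if (!is.null(design))
    cfg$design <- list(n_exposures = design$n_exposures,
                       exposure_s = design$exposure_s,
                       single_exposure_s = design$single_exposure_s)
  if (!is.null(known_dose)) cfg$known_dose <- known_dose
  yaml::write_yaml(cfg, path)
  invisible(path)
}
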