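#' Ground truth for a synthetic dosimetry experiment
#'
#' Describes a complete experiment — true location doses, true calibration
#' factor, and the size of every random-error component — from which
#' [generate_experiment()] draws raw read-outs with known truth. This is
#' what makes every stage of the pipeline testable without access to any
#' real read-out data.
#'
#' @param layout a [phantom_layout()].
#' @param true_doses matrix of true absorbed doses in mGy, protocols in
#'   rows (named), locations in columns (named as in `layout`).
#' @param true_cf true mean calibration factor, pulses/mGy.
#' @param cf_spread_rsd_percent RSD of the per-dosimeter calibration
#'   factors around `true_cf` (\%).
#' @param background_mean_pulses named per-protocol true background level
#'   (pulses), or a scalar.
#' @param background_rsd_percent named per-protocol background read-out
#'   RSD (\%), or a scalar.
#' @param readout_model a [readout_rsd_model()] describing read-out noise.
#' @param generator_rsd_percent per-exposure generator output RSD (\%).
#'   (Recorded in the truth and used when simulating; the generated
#'   read-outs describe a completed protocol whose generator fluctuation
#'   has already averaged into the accumulated dose.)
#' @param design an [exposure_design()].
#' @param dosimeters_per_location dosimeters at each location.
#' @param n_calibration number of calibration dosimeters.
#' @param n_background background dosimeters per protocol.
#' @param known_dose calibration dose, mGy.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(layout, true_doses, true_cf = 1e7,
                            cf_spread_rsd_percent = 3.2,
                            background_mean_pulses = 3e4,
                            background_rsd_percent = c(P1 = 9.5, P2 = 4.6,
                                                       P3 = 8.6, P4 = 1.3),
                            readout_model = readout_rsd_model(4.57, -1.98e-7,
                                                              3.29e-15),
                            generator_rsd_percent = 2.4,
                            design = exposure_design(),
                            dosimeters_per_location = 2,
                            n_calibration = 53, n_background = 3,
                            known_dose = 2) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(readout_model, "readout_rsd_model"))
  true_doses <- as.matrix(true_doses)
  if (ncol(true_doses) != length(layout$locations))
    stop("columns of 'true_doses' must match the layout locations")
  if (is.null(rownames(true_doses)))
    rownames(true_doses) <- paste0("P", seq_len(nrow(true_doses)))
  if (is.null(colnames(true_doses)))
    colnames(true_doses) <- layout$locations
  if (!setequal(colnames(true_doses), layout$locations))
    stop("columns of 'true_doses' must match the layout locations")
  if (any(true_doses < 0)) stop("true doses must be >= 0")
  protocols <- rownames(true_doses)
  as_per_protocol <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      return(stats::setNames(rep(x, length(protocols)), protocols))
    miss <- setdiff(protocols, names(x))
    if (length(miss))
      stop("'", what, "' missing protocol(s): ", paste(miss, collapse = ", "))
    x[protocols]
  }
  background_mean_pulses <- as_per_protocol(background_mean_pulses,
                                            "background_mean_pulses")
  background_rsd_percent <- as_per_protocol(background_rsd_percent,
                                            "background_rsd_percent")
  if (cf_spread_rsd_percent < 0 || generator_rsd_percent < 0 ||
      any(background_rsd_percent < 0))
    stop("all RSDs must be >= 0")
  if (true_cf <= 0) stop("'true_cf' must be positive")
  structure(
    list(layout = layout, true_doses = true_doses, protocols = protocols,
         true_cf = true_cf, cf_spread_rsd_percent = cf_spread_rsd_percent,
         background_mean_pulses = background_mean_pulses,
         background_rsd_percent = background_rsd_percent,
         readout_model = readout_model,
         generator_rsd_percent = generator_rsd_percent,
         design = design,
         dosimeters_per_location = dosimeters_per_location,
         n_calibration = n_calibration, n_background = n_background,
         known_dose = known_dose),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic experiment truth\n")
  cat(sprintf("  %d protocols x %d locations x %d dosimeters, %g exposures\n",
              length(x$protocols), ncol(x$true_doses),
              x$dosimeters_per_location, x$design$n_exposures))
  cat(sprintf("  true CF %.4g pulses/mGy (spread %.3g%%), %d calibration TLDs\n",
              x$true_cf, x$cf_spread_rsd_percent, x$n_calibration))
  cat(sprintf("  true E per exposure: %s\n",
              paste(sprintf("%s=%.4g", x$protocols,
                            true_effective_dose(x)), collapse = ", ")))
  invisible(x)
}

#' Ground-truth effective dose per single exposure
#'
#' Deterministic evaluation of the dose chain on the true doses: what the
#' experiment would report with every error source at zero.
#'
#' @param truth a [synthetic_truth()].
#' @return Named numeric vector, one value per protocol.
#' @export
true_effective_dose <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ratio <- single_exposure_ratio(truth$design)
  vapply(truth$protocols, function(p) {
    td <- compute_tissue_doses(truth$true_doses[p, ], truth$layout)
    compute_effective_dose(td, truth$layout) / ratio
  }, numeric(1))
}

#' Default synthetic truth: a four-protocol cephalometric phantom study
#'
#' Emulates the structure of a lateral-cephalography phantom dose study:
#' 4 shielding protocols, 25 phantom locations with 2 dosimeters each,
#' 50 accumulated exposures of 5 s, reported per 0.6 s single exposure,
#' 3 background dosimeters per protocol and 53 calibration dosimeters.
#' The error components default to empirically quantified values
#' (calibration spread 3.2%; background spreads 9.5/4.6/8.6/1.3%;
#' quadratic read-out noise; generator fluctuation 2.4% per exposure).
#'
#' The true dose pattern across locations is illustrative (real patterns
#' are study-specific and unpublished): doses are log-spaced over the
#' pulse range in which the read-out noise model was fitted, so both the
#' high-noise (low signal) and low-noise (high signal) regimes are
#' exercised, and each protocol scales the pattern by a shielding factor.
#'
#' @param protocol_scale named per-protocol multiplier of the base dose
#'   pattern (default `c(P1=1, P2=0.85, P3=0.7, P4=0.55)`).
#' @param dose_range range of true location doses in mGy for the first
#'   protocol; with the default CF of 1e7 pulses/mGy this spans read-out
#'   values from 2.5e5 to 2.5e7 pulses.
#' @param ... overrides passed to [synthetic_truth()].
#' @return A [synthetic_truth()].
#' @export
default_truth <- function(protocol_scale = c(P1 = 1, P2 = 0.85,
                                             P3 = 0.7, P4 = 0.55),
                          dose_range = c(0.025, 2.5), ...) {
  layout <- default_layout()
  n_loc <- length(layout$locations)
  base <- exp(seq(log(dose_range[1]), log(dose_range[2]),
                  length.out = n_loc))
  true_doses <- outer(protocol_scale, base)
  dimnames(true_doses) <- list(names(protocol_scale), layout$locations)
  args <- list(layout = layout, true_doses = true_doses, ...)
  if (is.null(args$background_rsd_percent) &&
      !identical(sort(names(protocol_scale)), sort(c("P1", "P2", "P3", "P4"))))
    args$background_rsd_percent <- 5
  do.call(synthetic_truth, args)
}

#' Generate a synthetic measurement set from a ground truth
#'
#' Draws a complete raw dataset with the statistical structure described
#' by the truth:
#' \itemize{
#'   \item each exposed dosimeter's noise-free read-out is
#'     `true_dose * true_cf + background`; the read-out noise model,
#'     evaluated at that noise-free value, gives the RSD of the single
#'     perturbation applied to it. The noise curve is the \emph{total}
#'     reading-level noise — in real data it is fitted from observed
#'     dosimeter pairs and therefore already subsumes dosimeter-to-
#'     dosimeter sensitivity spread, so no separate per-dosimeter CF draw
#'     is added (that would double-count the spread);
#'   \item calibration read-outs are `known_dose * CF_dosimeter` for
#'     `n_calibration` dosimeters drawn with the CF spread;
#'   \item background read-outs are drawn around the per-protocol
#'     background mean with the per-protocol background RSD.
#' }
#' With every spread at zero the generated set reproduces the true
#' effective dose exactly through the deterministic pipeline.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed; the generated set is a deterministic function
#'   of `(truth, seed)`.
#' @return List with `measurements` (a [measurement_set()]), `truth_E`
#'   (named ground-truth effective dose per single exposure) and `truth`.
#' @export
generate_experiment <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    .generate_experiment_impl(truth)
  })
}

.generate_experiment_impl <- function(truth) {
  lay <- truth$layout
  k <- truth$dosimeters_per_location
  protocols <- truth$protocols
  n_loc <- length(lay$locations)

  clamp0 <- function(x) pmax(x, 0)

  # calibration set: per-dosimeter CFs around the true CF
  cal_cf <- truth$true_cf *
    (1 + truth$cf_spread_rsd_percent / 100 * stats::rnorm(truth$n_calibration))
  calibration <- data.frame(
    dosimeter_id = sprintf("C%02d", seq_len(truth$n_calibration)),
    pulses = clamp0(cal_cf * truth$known_dose))

  readings <- do.call(rbind, lapply(protocols, function(p) {
    grid <- expand.grid(position = seq_len(k), location = lay$locations,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    dose <- truth$true_doses[p, grid$location]
    clean <- dose * truth$true_cf + truth$background_mean_pulses[[p]]
    rsd <- evaluate_readout_rsd(truth$readout_model, clean,
                                warn_outside = FALSE)
    data.frame(protocol = p, location = grid$location,
               position = grid$position,
               pulses = clamp0(perturb(clean, rsd)))
  }))

  background <- do.call(rbind, lapply(protocols, function(p)
    data.frame(protocol = p,
               dosimeter_id = sprintf("B%d", seq_len(truth$n_background)),
               pulses = clamp0(perturb(
                 rep(truth$background_mean_pulses[[p]], truth$n_background),
                 truth$background_rsd_percent[[p]])))))

  ms <- measurement_set(readings, calibration, background,
                        known_dose = truth$known_dose,
                        design = truth$design)
  list(measurements = ms, truth_E = true_effective_dose(truth),
       truth = truth)
}

#' Error model matching a synthetic truth
#'
#' The error model whose components equal the spreads the generator
#' injected — what a perfectly informed analyst would feed to
#' [run_simulation()] on data from [generate_experiment()].
#'
#' @param truth a [synthetic_truth()].
#' @param ... overrides passed to [error_model()] (e.g. error modes).
#' @return An [error_model()].
#' @export
truth_error_model <- function(truth, ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  args <- list(cf_rsd_percent = truth$cf_spread_rsd_percent,
               background_rsd_percent = truth$background_rsd_percent,
               readout_model = truth$readout_model,
               generator_rsd_percent = truth$generator_rsd_percent)
  args[names(list(...))] <- list(...)
  do.call(error_model, args)
}
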