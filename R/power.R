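#' A candidate experimental design for prospective error analysis
#'
#' @param dosimeters_per_location dosimeters at each phantom location.
#' @param exposures_per_protocol exposures accumulated per protocol.
#' @param relative_difference true relative difference (\%) in effective
#'   dose between the two compared protocols, injected by the generator.
#' @param alpha significance level for the paired comparison.
#' @param replicates number of independently generated experiments.
#' @param cycles Monte Carlo cycles per simulated experiment.
#' @return Object of class `design_variant`.
#' @export
design_variant <- function(dosimeters_per_location = 2,
                           exposures_per_protocol = 50,
                           relative_difference = 0,
                           alpha = 0.05, replicates = 200, cycles = 2000) {
  if (dosimeters_per_location < 1 || exposures_per_protocol < 1 ||
      replicates < 1 || cycles < 1)
    stop("counts must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (relative_difference < 0)
    stop("'relative_difference' must be >= 0")
  structure(list(dosimeters_per_location = dosimeters_per_location,
                 exposures_per_protocol = exposures_per_protocol,
                 relative_difference = relative_difference,
                 alpha = alpha, replicates = replicates, cycles = cycles),
            class = "design_variant")
}

# Truth restricted to the two compared protocols, with the variant's
# design applied: protocol B's doses are protocol A's scaled by
# (1 + relative_difference/100).
.variant_truth <- function(truth, variant, protocol_a, protocol_b) {
  doses <- rbind(truth$true_doses[protocol_a, ],
                 truth$true_doses[protocol_a, ] *
                   (1 + variant$relative_difference / 100))
  rownames(doses) <- c(protocol_a, protocol_b)
  design <- truth$design
  design$n_exposures <- variant$exposures_per_protocol
  synthetic_truth(
    layout = truth$layout, true_doses = doses, true_cf = truth$true_cf,
    cf_spread_rsd_percent = truth$cf_spread_rsd_percent,
    background_mean_pulses = truth$background_mean_pulses[
      c(protocol_a, protocol_b)],
    background_rsd_percent = truth$background_rsd_percent[
      c(protocol_a, protocol_b)],
    readout_model = truth$readout_model,
    generator_rsd_percent = truth$generator_rsd_percent,
    design = design,
    dosimeters_per_location = variant$dosimeters_per_location,
    n_calibration = truth$n_calibration,
    n_background = truth$n_background,
    known_dose = truth$known_dose)
}

.replicate_sims <- function(truth, variant, seed, protocol_a, protocol_b) {
  tv <- .variant_truth(truth, variant, protocol_a, protocol_b)
  em <- truth_error_model(tv)
  lapply(seq_len(variant$replicates), function(i) {
    s <- if (is.null(seed)) NULL else .substream_seed(seed, paste0("rep:", i))
    gen <- generate_experiment(tv, seed = s)
    run_simulation(gen$measurements, tv$layout, em,
                   cycles = variant$cycles, seed = s)
  })
}

#' Random error of the effective dose under a candidate design
#'
#' Generates `replicates` synthetic experiments under the design variant,
#' runs the Monte Carlo error simulation on each, and averages the
#' resulting RSD of the effective dose. Answers design questions such as
#' "how much does the error grow with one dosimeter per location instead
#' of two?" or "what does quadrupling the exposures buy?" before any
#' phantom is irradiated.
#'
#' @param truth a [synthetic_truth()] describing the anticipated study.
#' @param variant a [design_variant()].
#' @param seed integer master seed.
#' @param protocol_a,protocol_b the two protocols carried into the
#'   variant (defaults: the truth's first two).
#' @return List: `rsd_percent` (mean over replicates and protocols),
#'   `per_protocol` (mean RSD per protocol), `replicates`.
#' @export
estimate_rsd_for_design <- function(truth, variant, seed = NULL,
                                    protocol_a = truth$protocols[1],
                                    protocol_b = truth$protocols[2]) {
  sims <- .replicate_sims(truth, variant, seed, protocol_a, protocol_b)
  rsds <- t(vapply(sims, function(s)
    stats::setNames(s$summaries$rsd_percent, s$summaries$protocol),
    numeric(2)))
  per_protocol <- colMeans(rsds)
  list(rsd_percent = mean(per_protocol), per_protocol = per_protocol,
       replicates = variant$replicates)
}

#' Power to detect a protocol difference under a candidate design
#'
#' The generator injects a true relative difference between two protocols;
#' each replicate experiment is simulated and the paired comparison
#' ([compare_protocols()]) is run. Power is the fraction of replicates in
#' which the percentile interval of the paired differences excludes 0.
#' With `relative_difference = 0` this estimates the type-I error, which
#' should match `alpha`.
#'
#' @inheritParams estimate_rsd_for_design
#' @return List: `power`, `rejections`, `replicates`, `alpha`,
#'   `relative_difference`.
#' @export
estimate_power <- function(truth, variant, seed = NULL,
                           protocol_a = truth$protocols[1],
                           protocol_b = truth$protocols[2]) {
  if (variant$replicates < 20)
    warning("fewer than 20 replicates: power estimate is unstable")
  sims <- .replicate_sims(truth, variant, seed, protocol_a, protocol_b)
  rej <- vapply(sims, function(s)
    compare_protocols(s, protocol_b, protocol_a,
                      alpha = variant$alpha)$significant,
    logical(1))
  list(power = mean(rej), rejections = sum(rej),
       replicates = variant$replicates, alpha = variant$alpha,
       relative_difference = variant$relative_difference)
}

#' Sweep a grid of design variants
#'
#' @param truth a [synthetic_truth()].
#' @param grid data frame of variant fields (missing fields take the
#'   [design_variant()] defaults), one row per candidate design.
#' @param seed integer master seed (each row gets a derived substream).
#' @param estimate_power_too also estimate power per row (slower).
#' @return `grid` with columns `rsd_percent` (and `power` if requested)
#'   appended.
#' @export
power_grid <- function(truth, grid, seed = NULL,
                       estimate_power_too = TRUE) {
  grid <- as.data.frame(grid)
  out <- grid
  out$rsd_percent <- NA_real_
  if (estimate_power_too) out$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    v <- do.call(design_variant, as.list(grid[i, , drop = FALSE]))
    s <- if (is.null(seed)) NULL else .substream_seed(seed, paste0("row:", i))
    out$rsd_percent[i] <- estimate_rsd_for_design(truth, v, seed = s)$rsd_percent
    if (estimate_power_too)
      out$power[i] <- estimate_power(truth, v, seed = s)$power
  }
  out
}
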