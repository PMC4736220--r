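# Deterministic substream seeding: every (component, protocol) pair draws
# from its own seeded stream, so adding or removing a protocol does not
# disturb any other protocol's draws.
.substream_seed <- function(seed, key) {
  h <- seed %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Run expr without disturbing the caller's RNG state.
.with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Draw random-error perturbations of a measured value
#'
#' Random error is modelled as a normal distribution around the assumed
#' true value: the draw is `Normal(mean = value, sd = value * rsd / 100)`.
#' An RSD of 0 — or a value of 0, whose absolute SD vanishes — returns the
#' value unchanged.
#'
#' @param value measured value(s).
#' @param rsd_percent relative standard deviation in percent (>= 0),
#'   recycled against `value`.
#' @param z optional standard-normal draws to use (recycled); by default
#'   drawn from the current RNG.
#' @return Perturbed value(s).
#' @export
perturb <- function(value, rsd_percent, z = NULL) {
  if (any(rsd_percent < 0)) stop("'rsd_percent' must be >= 0")
  if (is.null(z)) z <- stats::rnorm(length(value))
  value * (1 + rsd_percent / 100 * z)
}

#' Monte Carlo random-error simulation of the dose experiment
#'
#' Repeats the full effective-dose calculation `cycles` times. In every
#' cycle each measured quantity is perturbed according to its quantified
#' random error:
#' \itemize{
#'   \item one calibration-factor perturbation, drawn once and shared by
#'     all protocols (the CF was determined once for the whole experiment;
#'     sharing it is what keeps protocol differences from having their
#'     error overestimated);
#'   \item one background perturbation per protocol;
#'   \item one perturbation per dosimeter reading, with the RSD given by
#'     the read-out noise model evaluated at that reading;
#'   \item one perturbation of the protocol-to-single-exposure conversion
#'     ratio per protocol, with RSD `generator_rsd / sqrt(n_exposures)`.
#' }
#' Each (component, protocol) pair draws from its own seeded substream,
#' so results are reproducible given `(seed, cycles)` and adding a
#' protocol does not disturb the draws of the others.
#'
#' @param measurements a [measurement_set()].
#' @param layout a [phantom_layout()].
#' @param error_model an [error_model()]; its per-protocol background RSDs
#'   must cover the measurement set's protocols (a scalar is recycled).
#' @param cycles number of Monte Carlo cycles (default 10000).
#' @param seed integer master seed; `NULL` uses the current RNG state
#'   (then the run is not reproducible by seed).
#' @param ci_level level of the empirical percentile confidence intervals.
#' @param shared_cf draw one CF perturbation per cycle shared by all
#'   protocols (default TRUE, matching how a single calibration serves the
#'   whole experiment). `FALSE` draws an independent CF per protocol,
#'   which inflates the error of between-protocol differences; provided
#'   for studying exactly that effect.
#' @param clamp_negative clamp negative perturbed pulse values and doses
#'   to 0 (physical non-negativity); occurrences are counted in the
#'   result's `diagnostics`.
#' @return An object of class `dose_sim`: list with `samples`
#'   (cycles x protocols matrix of effective dose per single exposure),
#'   `summaries` (per-protocol data frame), `comparisons` (all pairwise
#'   [compare_protocols()] results), `E_deterministic`, `cycles`, `seed`,
#'   `ci_level`, `shared_cf`, `diagnostics`.
#' @seealso [summarize_samples()], [compare_protocols()]
#' @export
run_simulation <- function(measurements, layout, error_model,
                           cycles = 10000, seed = NULL, ci_level = 0.95,
                           shared_cf = TRUE, clamp_negative = TRUE) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(layout, "phantom_layout"),
            inherits(error_model, "error_model"))
  if (cycles < 1) stop("'cycles' must be >= 1")
  validate_measurements(measurements, layout)
  .with_preserved_rng(
    .run_simulation_impl(measurements, layout, error_model, cycles, seed,
                         ci_level, shared_cf, clamp_negative))
}

.run_simulation_impl <- function(measurements, layout, em, cycles, seed,
                                 ci_level, shared_cf, clamp_negative) {
  draw_z <- function(key, n) {
    if (!is.null(seed)) set.seed(.substream_seed(seed, key))
    stats::rnorm(n)
  }
  protocols <- measurements$protocols
  design <- measurements$design
  cal <- compute_calibration(measurements$calibration,
                             measurements$known_dose)
  ratio <- single_exposure_ratio(design)
  ratio_rsd <- propagate_mean_rsd(em$generator_rsd_percent,
                                  design$n_exposures)

  bg_rsds <- em$background_rsd_percent
  if (is.null(names(bg_rsds))) {
    if (length(bg_rsds) == 1L)
      bg_rsds <- stats::setNames(rep(bg_rsds, length(protocols)), protocols)
    else stop("'background_rsd_percent' must be named by protocol ",
              "or a scalar")
  }
  miss <- setdiff(protocols, names(bg_rsds))
  if (length(miss))
    stop("error model has no background RSD for protocol(s): ",
         paste(miss, collapse = ", "))

  cf_rsd_eff <- if (em$cf_error_mode == "mean-of-n")
    em$cf_rsd_percent / sqrt(cal$n) else em$cf_rsd_percent

  cf_shared <- if (shared_cf)
    perturb(cal$mean_cf, cf_rsd_eff, draw_z("cf", cycles))

  # tissue aggregation: E = dose_to_uSv * w' Tm locmean, Tm row t =
  # fraction_t / |locations_t| over its locations
  n_loc <- length(layout$locations)
  Tm <- matrix(0, length(layout$tissues), n_loc,
               dimnames = list(names(layout$tissues), layout$locations))
  for (tn in names(layout$tissues)) {
    t <- layout$tissues[[tn]]
    Tm[tn, t$locations] <- Tm[tn, t$locations] +
      t$fraction / length(t$locations)
  }
  w <- vapply(layout$tissues, `[[`, numeric(1), "weight")
  ew <- as.numeric(w %*% Tm) * layout$dose_to_uSv # per-location E weights

  samples <- matrix(NA_real_, cycles, length(protocols),
                    dimnames = list(NULL, protocols))
  diag_counts <- c(negative_pulses = 0, negative_doses = 0,
                   negative_background = 0)

  for (p in protocols) {
    rd <- measurements$readings[measurements$readings$protocol == p, ]
    bgp <- measurements$background$pulses[
      measurements$background$protocol == p]
    bg <- compute_background(bgp)
    bg_rsd_eff <- if (em$background_error_mode == "mean-of-n")
      bg_rsds[[p]] / sqrt(length(bgp)) else bg_rsds[[p]]
    bg_draws <- perturb(bg$mean_bg_pulses, bg_rsd_eff,
                        draw_z(paste0("background:", p), cycles))
    if (clamp_negative && any(bg_draws < 0)) {
      diag_counts["negative_background"] <-
        diag_counts["negative_background"] + sum(bg_draws < 0)
      bg_draws[bg_draws < 0] <- 0
    }

    n_read <- nrow(rd)
    rsd_i <- evaluate_readout_rsd(em$readout_model, rd$pulses,
                                  warn_outside = FALSE)
    Z <- matrix(draw_z(paste0("readout:", p), n_read * cycles),
                n_read, cycles)
    pert <- rd$pulses * (1 + rsd_i / 100 * Z)
    if (clamp_negative && any(pert < 0)) {
      diag_counts["negative_pulses"] <-
        diag_counts["negative_pulses"] + sum(pert < 0)
      pert[pert < 0] <- 0
    }

    # per-location averaging of the k dosimeters
    locf <- factor(as.character(rd$location), levels = layout$locations)
    M <- matrix(0, n_loc, n_read)
    M[cbind(as.integer(locf), seq_len(n_read))] <- 1
    M <- M / rowSums(M)
    locmean <- M %*% pert                       # n_loc x cycles

    cf_draws <- if (shared_cf) cf_shared
      else perturb(cal$mean_cf, cf_rsd_eff,
                   draw_z(paste0("cf:", p), cycles))
    if (any(cf_draws <= 0))
      stop("a perturbed calibration factor was non-positive; the CF RSD ",
           "is too large for a normal error model")

    doses <- sweep(locmean, 2, bg_draws, "-")
    doses <- sweep(doses, 2, cf_draws, "/")
    if (clamp_negative && any(doses < 0)) {
      diag_counts["negative_doses"] <-
        diag_counts["negative_doses"] + sum(doses < 0)
      doses[doses < 0] <- 0
    }

    E_protocol <- as.numeric(ew %*% doses)
    ratio_draws <- perturb(ratio, ratio_rsd,
                           draw_z(paste0("generator:", p), cycles))
    if (any(ratio_draws <= 0))
      stop("a perturbed conversion ratio was non-positive; the generator ",
           "RSD is too large for a normal error model")
    samples[, p] <- E_protocol / ratio_draws
  }

  if (any(!is.finite(samples)))
    stop("non-finite effective dose produced in cycle(s) ",
         paste(utils::head(which(!is.finite(rowSums(samples)))),
               collapse = ", "))

  res <- structure(
    list(samples = samples, cycles = cycles, seed = seed,
         ci_level = ci_level, shared_cf = shared_cf,
         E_deterministic = effective_dose(measurements, layout),
         calibration = cal, error_model = em,
         diagnostics = as.list(diag_counts)),
    class = "dose_sim")
  res$summaries <- do.call(rbind, lapply(protocols, function(p) {
    s <- if (cycles >= 2) summarize_samples(samples[, p], ci_level)
         else list(mean = samples[1, p], sd = 0, rsd_percent = 0,
                   ci_lower = samples[1, p], ci_upper = samples[1, p],
                   min = samples[1, p], q1 = samples[1, p],
                   median = samples[1, p], q3 = samples[1, p],
                   max = samples[1, p], n = 1L)
    data.frame(protocol = p, as.data.frame(s))
  }))
  if (length(protocols) >= 2L) {
    prs <- utils::combn(protocols, 2, simplify = FALSE)
    res$comparisons <- lapply(prs, function(pr)
      compare_protocols(res, pr[1], pr[2]))
    names(res$comparisons) <- vapply(prs, paste, "", collapse = " - ")
  } else res$comparisons <- list()
  res
}

#' Summary statistics of a sampled dose distribution
#'
#' Mean, sample SD, RSD, the empirical percentile confidence interval and
#' the five-number summary used for box plots. Quantiles use linear
#' interpolation (`stats::quantile` type 7) so results are bit-exactly
#' reproducible.
#'
#' @param samples numeric vector (>= 2 values).
#' @param ci_level confidence level for the percentile interval.
#' @return Named list: `mean`, `sd`, `rsd_percent`, `ci_lower`,
#'   `ci_upper`, `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
summarize_samples <- function(samples, ci_level = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("at least 2 samples are required")
  a <- (1 - ci_level) / 2
  q <- stats::quantile(samples, c(a, 1 - a, 0, 0.25, 0.5, 0.75, 1),
                       type = 7, names = FALSE)
  m <- mean(samples)
  s <- stats::sd(samples)
  list(mean = m, sd = s,
       rsd_percent = if (m != 0) 100 * s / m else NA_real_,
       ci_lower = q[1], ci_upper = q[2],
       min = q[3], q1 = q[4], median = q[5], q3 = q[6], max = q[7],
       n = length(samples))
}

#' Paired comparison of two protocols from one simulation run
#'
#' Because both protocols were recomputed in the same cycles with the
#' same calibration-factor draw, the cycle-wise differences carry only
#' the error that actually distinguishes the protocols. The comparison
#' reports the mean difference, its empirical percentile interval, and
#' whether the interval excludes 0 ("significant" at level `alpha`).
#'
#' @param result a `dose_sim` from [run_simulation()]. Both protocols must
#'   come from this same run; samples from different runs have no paired
#'   structure and are rejected.
#' @param protocol_a,protocol_b protocol names in `result`.
#' @param alpha significance level (percentile interval at `1 - alpha`).
#' @return Object of class `protocol_comparison`: `mean_diff`, `ci`
#'   (length 2), `significant`, `sign_agreement` (fraction of cycles whose
#'   difference has the sign of the mean difference), `alpha`, protocols.
#' @export
compare_protocols <- function(result, protocol_a, protocol_b,
                              alpha = 0.05) {
  if (!inherits(result, "dose_sim"))
    stop("'result' must be a dose_sim; protocols can only be compared ",
         "within a single simulation run (shared calibration draws)")
  for (p in c(protocol_a, protocol_b))
    if (!p %in% colnames(result$samples))
      stop("protocol '", p, "' was not simulated in this run")
  d <- result$samples[, protocol_a] - result$samples[, protocol_b]
  ci <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), type = 7,
                        names = FALSE)
  md <- mean(d)
  structure(
    list(protocol_a = protocol_a, protocol_b = protocol_b,
         mean_diff = md, ci = ci,
         significant = ci[1] > 0 || ci[2] < 0,
         sign_agreement = if (md != 0) mean(sign(d) == sign(md))
                          else NA_real_,
         sd_diff = stats::sd(d), alpha = alpha),
    class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s - %s: mean difference %.4g [%.4g, %.4g] (%.0f%% CI)\n",
              x$protocol_a, x$protocol_b, x$mean_diff, x$ci[1], x$ci[2],
              100 * (1 - x$alpha)))
  cat(if (x$significant) "  interval excludes 0: difference is significant\n"
      else "  interval includes 0: no significant difference\n")
  invisible(x)
}

#' @export
print.dose_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo dose simulation: %d cycles, %d protocol(s)%s\n",
              x$cycles, ncol(x$samples),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  calibration draw %s across protocols\n",
              if (x$shared_cf) "shared" else "independent"))
  s <- x$summaries
  cat("\nEffective dose per single exposure:\n")
  print(data.frame(protocol = s$protocol,
                   mean = signif(s$mean, digits),
                   sd = signif(s$sd, digits),
                   rsd_percent = signif(s$rsd_percent, 3),
                   ci_lower = signif(s$ci_lower, digits),
                   ci_upper = signif(s$ci_upper, digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.dose_sim <- function(object, ...) {
  structure(list(summaries = object$summaries,
                 comparisons = object$comparisons,
                 cycles = object$cycles,
                 diagnostics = object$diagnostics),
            class = "summary.dose_sim")
}

#' @export
print.summary.dose_sim <- function(x, ...) {
  cat("Per-protocol effective dose (", x$cycles, " cycles):\n", sep = "")
  print(x$summaries, row.names = FALSE)
  if (length(x$comparisons)) {
    cat("\nPairwise protocol comparisons:\n")
    for (cp in x$comparisons) print(cp)
  }
  cl <- unlist(x$diagnostics)
  if (any(cl > 0))
    cat("\nClamped to 0:",
        paste(sprintf("%s=%d", names(cl)[cl > 0], cl[cl > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Box plots of the simulated effective-dose distributions
#'
#' @param x a `dose_sim`.
#' @param type `"box"` for per-protocol box plots, `"hist"` for a lattice
#'   of histograms.
#' @param ... passed to the underlying graphics call.
#' @export
plot.dose_sim <- function(x, type = c("box", "hist"), ...) {
  type <- match.arg(type)
  if (type == "box") {
    graphics::boxplot(x$samples, ylab = "E per exposure",
                      xlab = "protocol", ...)
  } else {
    p <- colnames(x$samples)
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(p)))
    on.exit(graphics::par(old))
    for (pn in p)
      graphics::hist(x$samples[, pn], main = pn,
                     xlab = "E per exposure", ...)
  }
  invisible(x)
}

#' Bundle an experiment for simulation
#'
#' Convenience container tying a measurement set, a layout and an error
#' model together, so the Monte Carlo run reads as
#' `simulate(experiment, nsim, seed)`.
#'
#' @param measurements a [measurement_set()].
#' @param layout a [phantom_layout()].
#' @param error_model an [error_model()]; default estimates it from the
#'   measurements via [estimate_error_model()].
#' @return Object of class `dose_experiment`.
#' @export
dose_experiment <- function(measurements, layout,
                            error_model = estimate_error_model(measurements)) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(layout, "phantom_layout"),
            inherits(error_model, "error_model"))
  validate_measurements(measurements, layout)
  structure(list(measurements = measurements, layout = layout,
                 error_model = error_model),
            class = "dose_experiment")
}

#' @export
print.dose_experiment <- function(x, ...) {
  print(x$measurements)
  print(x$layout)
  print(x$error_model)
  invisible(x)
}

#' @rdname run_simulation
#' @param object a [dose_experiment()].
#' @param nsim number of Monte Carlo cycles.
#' @param ... passed to [run_simulation()].
#' @export
simulate.dose_experiment <- function(object, nsim = 10000, seed = NULL,
                                     ...) {
  run_simulation(object$measurements, object$layout, object$error_model,
                 cycles = nsim, seed = seed, ...)
}
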