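#' Relative standard deviation of a set of read-outs
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation; the
#' universal error unit of the framework. For a dosimeter pair this equals
#' `100 * |difference| / (sqrt(2) * mean)`.
#'
#' @param values numeric vector (>= 2 values, positive mean).
#' @return RSD in percent.
#' @examples
#' pair_rsd(c(90, 110)) # ~14.14
#' @export
pair_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 values are required")
  m <- mean(values)
  if (m <= 0) stop("mean of values must be positive")
  100 * stats::sd(values) / m
}

#' Quadratic model of read-out noise versus read-out value
#'
#' The precision of the oven read-out depends on the signal size: the
#' higher the pulse count, the lower its relative spread. The relation is
#' modelled as `RSD(%) = a0 + a1 * value + a2 * value^2` over the range of
#' values it was fitted on. Models that predict a non-positive RSD
#' anywhere inside their valid range are rejected.
#'
#' @param a0,a1,a2 polynomial coefficients (RSD in percent, value in
#'   pulses).
#' @param valid_range length-2 numeric, the pulse-count range over which
#'   the model holds.
#' @param fit optionally, the `lm` fit the coefficients came from
#'   (kept for standard errors and diagnostics).
#' @return An object of class `readout_rsd_model`.
#' @seealso [fit_readout_rsd_model()], [evaluate_readout_rsd()]
#' @export
readout_rsd_model <- function(a0, a1 = 0, a2 = 0,
                              valid_range = c(0, 3e7), fit = NULL) {
  coefs <- c(a0 = as.numeric(a0), a1 = as.numeric(a1), a2 = as.numeric(a2))
  if (any(!is.finite(coefs))) stop("coefficients must be finite")
  valid_range <- sort(as.numeric(valid_range))
  m <- structure(list(coefficients = coefs, valid_range = valid_range,
                      fit = fit),
                 class = "readout_rsd_model")
  # positivity over the closed range: check endpoints and interior vertex.
  # Fitted models must be strictly positive; a hand-built constant-zero
  # model is legitimate (no read-out noise).
  crit <- valid_range
  if (coefs[["a2"]] != 0) {
    v <- -coefs[["a1"]] / (2 * coefs[["a2"]])
    if (v > valid_range[1] && v < valid_range[2]) crit <- c(crit, v)
  }
  lo <- min(.eval_quadratic(coefs, crit))
  if (lo < 0 || (lo <= 0 && !is.null(fit)))
    stop("model predicts non-positive RSD inside its valid range; ",
         "fit rejected")
  m
}

.eval_quadratic <- function(coefs, value)
  coefs[["a0"]] + coefs[["a1"]] * value + coefs[["a2"]] * value^2

#' @export
coef.readout_rsd_model <- function(object, ...) object$coefficients

#' @export
print.readout_rsd_model <- function(x, digits = 4, ...) {
  co <- x$coefficients
  cat(sprintf("Read-out noise model: RSD(%%) = %s %s %s * value %s %s * value^2\n",
              format(co[1], digits = digits),
              if (co[2] < 0) "-" else "+", format(abs(co[2]), digits = digits),
              if (co[3] < 0) "-" else "+", format(abs(co[3]), digits = digits)))
  cat(sprintf("  valid for read-out values in [%.4g, %.4g] pulses\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @export
predict.readout_rsd_model <- function(object, newdata, ...)
  evaluate_readout_rsd(object, newdata, warn_outside = FALSE)

#' Fit the quadratic read-out noise model by least squares
#'
#' Ordinary least squares of observed pair RSDs on the pair mean read-out
#' value. The pair mean is used as the abscissa because it is the only
#' choice symmetric in the two dosimeters of a pair.
#'
#' @param mean_value pulse-count abscissae (pair means), or a data frame
#'   with columns `mean_value` and `rsd_percent`.
#' @param rsd_percent observed RSDs (ignored when a data frame is given).
#' @return A [readout_rsd_model()] with the `lm` fit attached.
#' @export
fit_readout_rsd_model <- function(mean_value, rsd_percent = NULL) {
  if (is.data.frame(mean_value)) {
    rsd_percent <- mean_value$rsd_percent
    mean_value <- mean_value$mean_value
  }
  if (length(unique(mean_value)) < 3L)
    stop("at least 3 distinct read-out values are required for a ",
         "quadratic fit")
  d <- data.frame(value = as.numeric(mean_value),
                  rsd = as.numeric(rsd_percent))
  fit <- stats::lm(rsd ~ value + I(value^2), data = d)
  co <- stats::coef(fit)
  readout_rsd_model(co[[1]], co[[2]], co[[3]],
                    valid_range = range(d$value), fit = fit)
}

#' Evaluate the read-out noise model at a pulse count
#'
#' @param model a [readout_rsd_model()].
#' @param value pulse count(s), >= 0. Values outside the model's valid
#'   range trigger a warning (extrapolation).
#' @param warn_outside warn on extrapolation (default TRUE).
#' @return RSD in percent (vectorized over `value`).
#' @examples
#' m <- readout_rsd_model(4.57, -1.98e-7, 3.29e-15)
#' evaluate_readout_rsd(m, 0)    # 4.57
#' evaluate_readout_rsd(m, 1e6)  # 4.37529
#' @export
evaluate_readout_rsd <- function(model, value, warn_outside = TRUE) {
  stopifnot(inherits(model, "readout_rsd_model"))
  value <- as.numeric(value)
  if (any(value < 0)) stop("read-out values must be >= 0")
  if (warn_outside &&
      any(value < model$valid_range[1] | value > model$valid_range[2]))
    warning("evaluating read-out noise model outside its fitted range")
  .eval_quadratic(model$coefficients, value)
}

#' Random error of the mean of n repeated measurements
#'
#' If a single measurement has relative standard deviation `rsd_single`,
#' the mean of `n` independent repetitions has relative standard deviation
#' `rsd_single / sqrt(n)` (the standard propagation-of-error result,
#' `1/n * sqrt(n * rsd^2)`). This is how the per-exposure X-ray generator
#' fluctuation shrinks over a multi-exposure protocol.
#'
#' @param rsd_single RSD of one measurement, percent (>= 0).
#' @param n number of independent repetitions (>= 1).
#' @return RSD of the mean, percent.
#' @examples
#' propagate_mean_rsd(2.4, 50) # 0.34
#' @export
propagate_mean_rsd <- function(rsd_single, n) {
  if (!is.numeric(rsd_single) || any(rsd_single < 0))
    stop("'rsd_single' must be >= 0")
  if (!is.numeric(n) || any(n < 1))
    stop("'n' must be >= 1")
  rsd_single / sqrt(n)
}

#' Specification of every random-error source in the experiment
#'
#' Collects the four quantified error components: the calibration-factor
#' spread, the per-protocol background spread, the value-dependent
#' read-out noise, and the per-exposure generator output fluctuation.
#' Defaults are the components quantified from a four-protocol
#' cephalometric phantom study and serve as a worked example.
#'
#' `cf_error_mode` and `background_error_mode` control whether the error
#' applied to a *mean* of n read-outs is the raw component RSD
#' (`"direct"`) or the RSD of the mean, component RSD / sqrt(n)
#' (`"mean-of-n"`, default): the mean CF averages all calibration
#' dosimeters and the background averages its dosimeters, so their random
#' errors shrink accordingly.
#'
#' @param cf_rsd_percent RSD of the per-dosimeter calibration factors (\%).
#' @param background_rsd_percent named vector of per-protocol background
#'   RSDs (\%), or a scalar applied to every protocol.
#' @param readout_model a [readout_rsd_model()].
#' @param generator_rsd_percent RSD of the generator output for a single
#'   exposure (\%).
#' @param cf_error_mode,background_error_mode `"mean-of-n"` or `"direct"`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(cf_rsd_percent = 3.2,
                        background_rsd_percent = c(P1 = 9.5, P2 = 4.6,
                                                   P3 = 8.6, P4 = 1.3),
                        readout_model = readout_rsd_model(4.57, -1.98e-7,
                                                          3.29e-15),
                        generator_rsd_percent = 2.4,
                        cf_error_mode = c("mean-of-n", "direct"),
                        background_error_mode = c("mean-of-n", "direct")) {
  if (cf_rsd_percent < 0 || generator_rsd_percent < 0 ||
      any(background_rsd_percent < 0))
    stop("all RSDs must be >= 0")
  stopifnot(inherits(readout_model, "readout_rsd_model"))
  structure(
    list(cf_rsd_percent = cf_rsd_percent,
         background_rsd_percent = background_rsd_percent,
         readout_model = readout_model,
         generator_rsd_percent = generator_rsd_percent,
         cf_error_mode = match.arg(cf_error_mode),
         background_error_mode = match.arg(background_error_mode)),
    class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Random-error model\n")
  cat(sprintf("  calibration factor RSD: %.3g%% (%s)\n",
              x$cf_rsd_percent, x$cf_error_mode))
  cat("  background RSD (%):",
      paste(sprintf("%s=%.3g", names(x$background_rsd_percent),
                    x$background_rsd_percent), collapse = ", "),
      sprintf("(%s)\n", x$background_error_mode))
  co <- x$readout_model$coefficients
  cat(sprintf("  read-out RSD(value) = %.4g %+.3g*v %+.3g*v^2\n",
              co[1], co[2], co[3]))
  cat(sprintf("  generator output RSD per exposure: %.3g%%\n",
              x$generator_rsd_percent))
  invisible(x)
}

#' A random-error model with every component switched off
#'
#' Convenience for deterministic round trips and single-component studies:
#' start from no error at all and set only the component under study.
#'
#' @param protocols protocol names for the background component.
#' @return An [error_model()] with all RSDs 0, including a constant-zero
#'   read-out noise model.
#' @export
zero_error_model <- function(protocols = c("P1", "P2", "P3", "P4")) {
  bg <- stats::setNames(rep(0, length(protocols)), protocols)
  error_model(cf_rsd_percent = 0, background_rsd_percent = bg,
              readout_model = readout_rsd_model(0, 0, 0),
              generator_rsd_percent = 0)
}

#' Estimate the full error model from a measurement set
#'
#' Quantifies each random-error component from the raw read-outs:
#' \itemize{
#'   \item calibration RSD from the spread of per-dosimeter calibration
#'     factors ([compute_calibration()]);
#'   \item background RSD per protocol from the unexposed dosimeters;
#'   \item the read-out noise quadratic from the RSDs of all dosimeter
#'     pairs (one point per protocol x location, abscissa = pair mean),
#'     via [fit_readout_rsd_model()].
#' }
#' The generator output fluctuation cannot be estimated from dosimeter
#' read-outs (it is a property of the X-ray tube, measured separately)
#' and must be supplied.
#'
#' @param measurements a [measurement_set()].
#' @param generator_rsd_percent per-exposure generator RSD (\%).
#' @param ... passed on to [error_model()] (error modes).
#' @return An [error_model()]; the fitted read-out model keeps its `lm`
#'   fit, and the pair points are attached as attribute `"pair_points"`.
#' @export
estimate_error_model <- function(measurements, generator_rsd_percent = 2.4,
                                 ...) {
  stopifnot(inherits(measurements, "measurement_set"))
  cal <- compute_calibration(measurements$calibration,
                             measurements$known_dose)
  bg <- vapply(measurements$protocols, function(p)
    compute_background(measurements$background$pulses[
      measurements$background$protocol == p])$bg_rsd_percent,
    numeric(1))
  r <- measurements$readings
  key <- interaction(r$protocol, r$location, drop = TRUE)
  pts <- data.frame(
    mean_value = as.numeric(tapply(r$pulses, key, mean)),
    rsd_percent = as.numeric(tapply(r$pulses, key, pair_rsd)))
  model <- fit_readout_rsd_model(pts)
  em <- error_model(cf_rsd_percent = cal$cf_rsd_percent,
                    background_rsd_percent = bg,
                    readout_model = model,
                    generator_rsd_percent = generator_rsd_percent, ...)
  attr(em, "pair_points") <- pts
  em
}
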