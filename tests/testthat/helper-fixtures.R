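# Small hand-checkable fixtures used across the suite.

# Two locations, two tissues, no unit conversion: every number in the
# dose chain can be followed on paper.
toy_layout <- function() {
  phantom_layout(
    locations = c("locA", "locB"),
    tissues = list(
      thyroid = list(weight = 0.04, locations = "locA", fraction = 1),
      bone_marrow = list(weight = 0.12, locations = c("locA", "locB"),
                         fraction = 0.5)),
    dose_to_uSv = 1)
}

# One protocol measured at the toy layout. Pulses chosen so that with
# CF = 100 pulses/mGy and background 100 pulses:
#   locA: (1100 - 100)/100 = 10 mGy, locB: (2100 - 100)/100 = 20 mGy
#   thyroid = 10, bone_marrow = 0.5 * 15 = 7.5
#   E = 0.04*10 + 0.12*7.5 = 1.3, ratio = 50*5/0.6
toy_measurements <- function(design = exposure_design(50, 5, 0.6)) {
  measurement_set(
    readings = data.frame(
      protocol = "P1",
      location = rep(c("locA", "locB"), each = 2),
      position = rep(1:2, 2),
      pulses = c(1000, 1200, 2000, 2200)),
    calibration = data.frame(dosimeter_id = c("C1", "C2"),
                             pulses = c(1000, 1000)),
    background = data.frame(protocol = "P1",
                            dosimeter_id = c("B1", "B2", "B3"),
                            pulses = c(100, 100, 100)),
    known_dose = 10,
    design = design)
}

# Single-tissue single-location set with k dosimeters reading `pulses`
# each; background 0, exact calibration. E = w * pulses/cf / ratio.
single_site_measurements <- function(k = 2, pulses = 1e6, cf = 1e4,
                                     design = exposure_design(50, 5, 0.6)) {
  measurement_set(
    readings = data.frame(protocol = "P1", location = "loc1",
                          position = seq_len(k),
                          pulses = rep(pulses, k)),
    calibration = data.frame(dosimeter_id = c("C1", "C2"),
                             pulses = rep(cf, 2)),
    background = data.frame(protocol = "P1", dosimeter_id = "B1",
                            pulses = 0),
    known_dose = 1,
    design = design)
}

single_site_layout <- function() {
  phantom_layout(
    locations = "loc1",
    tissues = list(t1 = list(weight = 1, locations = "loc1", fraction = 1)),
    dose_to_uSv = 1)
}

# Error model with only the named component active, for the toy protocols.
only_component <- function(component = c("none", "cf", "background",
                                         "readout", "generator"),
                           rsd = 0, protocols = "P1", ...) {
  component <- match.arg(component)
  em <- zero_error_model(protocols)
  args <- list(cf_rsd_percent = 0,
               background_rsd_percent = em$background_rsd_percent,
               readout_model = readout_rsd_model(0, 0, 0),
               generator_rsd_percent = 0, ...)
  switch(component,
    none = NULL,
    cf = { args$cf_rsd_percent <- rsd },
    background = { args$background_rsd_percent[] <- rsd },
    readout = { args$readout_model <- readout_rsd_model(rsd, 0, 0) },
    generator = { args$generator_rsd_percent <- rsd })
  do.call(error_model, args)
}

# Noise-free truth: default study design with every spread at zero.
noiseless_truth <- function(...) {
  default_truth(cf_spread_rsd_percent = 0,
                background_rsd_percent = 0,
                readout_model = readout_rsd_model(0, 0, 0),
                generator_rsd_percent = 0, ...)
}

# Small-sample bias factor of the sample SD: E[s] = c4(n) * sigma.
c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
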