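test_that("calibration summary: mean CF and sample RSD", {
  # identity: readings equal to known_dose pulses at dose 1
  cal <- compute_calibration(c(1, 1, 1), known_dose = 1)
  expect_equal(cal$mean_cf, 1)
  expect_equal(cal$cf_rsd_percent, 0)

  # hand arithmetic: CFs {90, 110}, sd with n-1 denominator = 10*sqrt(2)
  cal <- compute_calibration(c(900, 1100), known_dose = 10)
  expect_equal(cal$mean_cf, 100)
  expect_equal(cal$per_dosimeter_cf, c(90, 110))
  expect_equal(cal$cf_rsd_percent, 100 * sd(c(90, 110)) / 100)
  expect_equal(cal$cf_rsd_percent, 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(cal$n, 2)

  expect_error(compute_calibration(100, known_dose = 1), "at least 2")
  expect_error(compute_calibration(c(1, 2), known_dose = 0), "positive")
  expect_error(compute_calibration(c(0, 2), known_dose = 1), "positive")
})

test_that("background: mean and sample RSD, single-reading fallback", {
  expect_equal(compute_background(c(100, 100, 100)),
               list(mean_bg_pulses = 100, bg_rsd_percent = 0))
  bg <- compute_background(c(90, 100, 110))
  expect_equal(bg$mean_bg_pulses, 100)
  expect_equal(bg$bg_rsd_percent, 10)
  expect_equal(compute_background(50)$bg_rsd_percent, 0)
  expect_true(is.na(compute_background(50, rsd_if_single = NA)$bg_rsd_percent))
  expect_error(compute_background(numeric(0)), "at least 1")
})

test_that("location doses: averaging, background subtraction, clamping", {
  rd <- data.frame(location = c("a", "a"), pulses = c(1000, 1000))
  expect_equal(unname(compute_location_doses(rd, 100, 0)), 10)

  rd <- data.frame(location = c("a", "a"), pulses = c(1000, 1200))
  expect_equal(unname(compute_location_doses(rd, 100, 100)), 10)

  rd <- data.frame(location = c("a", "a"), pulses = c(50, 50))
  expect_warning(d <- compute_location_doses(rd, 100, 100), "clamped")
  expect_equal(unname(d), 0)
  d <- suppressWarnings(
    compute_location_doses(rd, 100, 100, clamp_negative = FALSE))
  expect_equal(unname(d), -0.5)

  expect_error(
    compute_location_doses(rd, 100, 0, locations = c("a", "zz")), "zz")
})

test_that("tissue doses: location averaging times irradiated fraction", {
  lay <- toy_layout()
  d <- compute_tissue_doses(c(locA = 10, locB = 20), lay)
  expect_equal(d[["thyroid"]], 10)      # one location, fraction 1
  expect_equal(d[["bone_marrow"]], 7.5) # mean(10,20) * 0.5

  lay0 <- phantom_layout("x", list(t = list(weight = 1, locations = "x",
                                            fraction = 0)))
  expect_equal(unname(compute_tissue_doses(c(x = 5), lay0)), 0)
  expect_error(compute_tissue_doses(c(locA = 1), lay), "locB")
  expect_error(
    phantom_layout("x", list(t = list(weight = 1, locations = character(0),
                                      fraction = 1))),
    "zero locations")
})

test_that("effective dose: weighted summation and unit conversion", {
  lay <- toy_layout()
  expect_equal(compute_effective_dose(c(thyroid = 10, bone_marrow = 2), lay),
               0.04 * 10 + 0.12 * 2) # 0.64
  expect_equal(compute_effective_dose(c(thyroid = 0, bone_marrow = 0), lay), 0)
  one <- phantom_layout("x", list(t = list(weight = 1, locations = "x",
                                           fraction = 1)))
  expect_equal(compute_effective_dose(c(t = 5), one), 5)
  expect_error(compute_effective_dose(c(nope = 1), lay), "nope")

  # the conversion constant scales the report
  lay_uSv <- toy_layout()
  lay_uSv$dose_to_uSv <- 1000
  expect_equal(compute_effective_dose(c(thyroid = 10, bone_marrow = 2),
                                      lay_uSv), 640)
})

test_that("single-exposure conversion ratio", {
  expect_equal(round(single_exposure_ratio(exposure_design(50, 5, 0.6)), 1),
               416.7)
  expect_equal(single_exposure_ratio(exposure_design(1, 7, 7)), 1)
  expect_equal(single_exposure_ratio(exposure_design(10, 2, 0.5)), 40)
  expect_error(exposure_design(50, 0, 0.6), "positive")
  expect_error(exposure_design(0, 5, 0.6), ">= 1")
})

test_that("full deterministic chain matches the hand computation", {
  ms <- toy_measurements()
  lay <- toy_layout()
  # E = 1.3 (see helper), per exposure: / (250/0.6)
  expect_equal(compute_protocol_E(ms, lay, "P1"), 1.3 / (250 / 0.6),
               tolerance = 1e-12)
  expect_error(compute_protocol_E(ms, lay, "P9"), "unknown protocol")
})

test_that("chain invariances: CF scaling, linearity, monotonicity", {
  ms <- toy_measurements()
  lay <- toy_layout()
  e0 <- compute_protocol_E(ms, lay, "P1")

  # multiplying every pulse count cancels through the CF
  ms2 <- ms
  for (f in c("readings", "calibration", "background"))
    ms2[[f]]$pulses <- ms2[[f]]$pulses * 3.7
  expect_equal(compute_protocol_E(ms2, lay, "P1"), e0, tolerance = 1e-12)

  # scaling background-corrected doses scales E linearly: scale exposed
  # and background pulses while keeping the calibration fixed
  ms3 <- ms
  ms3$readings$pulses <- ms3$readings$pulses * 2
  ms3$background$pulses <- ms3$background$pulses * 2
  expect_equal(compute_protocol_E(ms3, lay, "P1"), 2 * e0,
               tolerance = 1e-12)

  # raising any one reading never decreases E
  for (i in seq_len(nrow(ms$readings))) {
    msi <- ms
    msi$readings$pulses[i] <- msi$readings$pulses[i] + 500
    expect_gte(compute_protocol_E(msi, lay, "P1"), e0)
  }
})

test_that("layout validation and weight-table check", {
  expect_error(
    phantom_layout("a", list(t = list(weight = 1, locations = "b",
                                      fraction = 1))),
    "unknown location")
  expect_error(
    phantom_layout("a", list(t = list(weight = 1, locations = "a",
                                      fraction = 1.2))),
    "fraction")
  expect_error(
    phantom_layout("a", list(t = list(weight = -1, locations = "a",
                                      fraction = 1))),
    "weighting factor")
  # full ICRP table sums to 1; the head/neck subset is flagged partial
  expect_equal(sum(icrp103_weights()), 1)
  expect_false(default_layout()$full_weight_table)
  expect_error(
    phantom_layout("a", list(t = list(weight = 0.5, locations = "a",
                                      fraction = 1)),
                   check_weights = "full"),
    "sum to")
})

test_that("measurement-set validation catches structural errors", {
  ms <- toy_measurements()
  expect_error(
    measurement_set(ms$readings, ms$calibration,
                    data.frame(protocol = "P2", dosimeter_id = "B1",
                               pulses = 1),
                    known_dose = 10),
    "background")
  bad <- ms$readings
  bad$pulses[1] <- -1
  expect_error(measurement_set(bad, ms$calibration, ms$background, 10),
               "non-negative")
  lay3 <- phantom_layout(c("locA", "locB", "locC"), toy_layout()$tissues)
  expect_error(validate_measurements(ms, lay3), "locC")
})
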