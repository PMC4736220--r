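test_that("perturbation draws: identity cases and CLT behaviour", {
  expect_equal(perturb(100, 0, z = 1.7), 100)
  expect_equal(perturb(0, 5, z = 2.3), 0)
  expect_error(perturb(100, -1), ">= 0")
  set.seed(2)
  x <- perturb(rep(100, 1e5), 5)
  expect_lt(abs(mean(x) - 100), 3 * 5 / sqrt(1e5))
  expect_lt(abs(sd(x) - 5), 3 * 5 / sqrt(2 * 1e5))
})

test_that("sample summaries: quantile rule and degenerate input", {
  s <- summarize_samples(c(1, 2, 3, 4, 5), ci_level = 0.9)
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)  # type-7 linear interpolation
  expect_equal(s$q3, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(s$rsd_percent, 100 * sd(1:5) / 3)

  sc <- summarize_samples(rep(7, 10))
  expect_equal(sc$sd, 0)
  expect_equal(sc$q1, sc$q3)
  expect_error(summarize_samples(1), "at least 2")

  set.seed(9)
  x <- rnorm(1e4, 10, 0.1)
  s <- summarize_samples(x, 0.95)
  expect_lt(s$ci_lower, 10)
  expect_gt(s$ci_upper, 10)
  expect_true(s$ci_lower <= s$median && s$median <= s$ci_upper)
})

test_that("all error sources at zero: degenerate deterministic simulation", {
  ms <- toy_measurements()
  lay <- toy_layout()
  sim <- run_simulation(ms, lay, only_component("none"), cycles = 50,
                        seed = 1)
  e0 <- compute_protocol_E(ms, lay, "P1")
  expect_equal(unique(as.numeric(sim$samples)), e0, tolerance = 1e-12)
  expect_equal(sim$summaries$sd, 0)
})

test_that("single active component reproduces its closed-form error", {
  lay <- single_site_layout()
  ms <- single_site_measurements(k = 2)
  cycles <- 10000

  # generator only: RSD of E ~ 2.4 / sqrt(50) = 0.34
  em <- only_component("generator", 2.4)
  sim <- run_simulation(ms, lay, em, cycles = cycles, seed = 3)
  expected <- propagate_mean_rsd(2.4, 50)
  expect_lt(abs(sim$summaries$rsd_percent - expected),
            3 * expected / sqrt(2 * cycles))

  # read-out noise only, constant RSD r, k dosimeters: RSD of E ~ r/sqrt(k)
  for (k in c(1, 2, 4)) {
    msk <- single_site_measurements(k = k)
    simk <- run_simulation(msk, lay, only_component("readout", 5),
                           cycles = cycles, seed = 4)
    expected <- 5 / sqrt(k)
    expect_lt(abs(simk$summaries$rsd_percent - expected),
              3 * expected / sqrt(2 * cycles))
  }

  # calibration only, direct mode: E ~ 1/CF-draw, RSD of E ~ cf rsd
  sim <- run_simulation(ms, lay, only_component("cf", 2,
                                                cf_error_mode = "direct"),
                        cycles = cycles, seed = 5)
  expect_lt(abs(sim$summaries$rsd_percent - 2), 3 * 2 / sqrt(2 * cycles))

  # mean-of-n mode shrinks the applied CF error by sqrt(n_calibration)
  sim2 <- run_simulation(ms, lay, only_component("cf", 2),
                         cycles = cycles, seed = 5)
  expected <- 2 / sqrt(2) # 2 calibration dosimeters in the fixture
  expect_lt(abs(sim2$summaries$rsd_percent - expected),
            3 * expected / sqrt(2 * cycles))
})

test_that("delta-method composition of all component errors", {
  # single site, no clamping regime: E = w * (R - B)/C / G with
  # independent relative errors; linearization gives the quadrature sum
  # scaled by the background-free lever arm.
  lay <- single_site_layout()
  k <- 2
  ms <- single_site_measurements(k = k, pulses = 1e6, cf = 1e4)
  cycles <- 10000
  em <- error_model(cf_rsd_percent = 1, background_rsd_percent = 0.8,
                    readout_model = readout_rsd_model(1.5),
                    generator_rsd_percent = 2.4,
                    cf_error_mode = "direct",
                    background_error_mode = "direct")
  # background is 0 pulses in the fixture, so its perturbation vanishes
  sim <- run_simulation(ms, lay, em, cycles = cycles, seed = 6)
  expected <- sqrt(1^2 + (1.5 / sqrt(k))^2 + propagate_mean_rsd(2.4, 50)^2)
  expect_lt(abs(sim$summaries$rsd_percent - expected),
            3 * expected / sqrt(2 * cycles))
})

test_that("simulation is bit-reproducible and substreams are stable", {
  tr <- default_truth()
  gen <- generate_experiment(tr, seed = 8)
  em <- truth_error_model(tr)
  s1 <- run_simulation(gen$measurements, tr$layout, em, cycles = 300,
                       seed = 21)
  s2 <- run_simulation(gen$measurements, tr$layout, em, cycles = 300,
                       seed = 21)
  expect_identical(s1$samples, s2$samples)

  # dropping a protocol leaves the remaining protocols' draws untouched
  ms13 <- gen$measurements
  keep <- ms13$readings$protocol %in% c("P1", "P3")
  ms13$readings <- ms13$readings[keep, ]
  ms13$background <- ms13$background[
    ms13$background$protocol %in% c("P1", "P3"), ]
  ms13$protocols <- c("P1", "P3")
  s3 <- run_simulation(ms13, tr$layout, em, cycles = 300, seed = 21)
  expect_identical(s3$samples[, "P1"], s1$samples[, "P1"])
  expect_identical(s3$samples[, "P3"], s1$samples[, "P3"])

  # a longer run extends, not reshuffles, the cycle stream
  s4 <- run_simulation(gen$measurements, tr$layout, em, cycles = 600,
                       seed = 21)
  expect_identical(s4$samples[1:300, ], s1$samples)
})

test_that("estimate stabilizes between half and full cycle budget", {
  tr <- default_truth()
  gen <- generate_experiment(tr, seed = 13)
  em <- truth_error_model(tr)
  half <- run_simulation(gen$measurements, tr$layout, em, cycles = 5000,
                         seed = 22)
  full <- run_simulation(gen$measurements, tr$layout, em, cycles = 10000,
                         seed = 22)
  for (p in tr$protocols) {
    r5 <- half$summaries$rsd_percent[half$summaries$protocol == p]
    r10 <- full$summaries$rsd_percent[full$summaries$protocol == p]
    expect_lt(abs(r5 - r10), 3 * r10 / sqrt(2 * 5000))
  }
})

test_that("paired comparison: identical data, injected difference, contract", {
  # two protocols with identical true doses: difference straddles 0
  tr0 <- default_truth(protocol_scale = c(A = 1, B = 1),
                       background_mean_pulses = 3e4,
                       background_rsd_percent = c(A = 5, B = 5))
  gen0 <- generate_experiment(noiseless_truth(
    protocol_scale = c(A = 1, B = 1)), seed = 31)
  em <- truth_error_model(tr0)
  sim0 <- run_simulation(gen0$measurements, tr0$layout, em, cycles = 2000,
                         seed = 32)
  cmp0 <- compare_protocols(sim0, "A", "B")
  expect_false(cmp0$significant)
  expect_true(cmp0$ci[1] < 0 && cmp0$ci[2] > 0)

  # a 10% true difference with small errors is detected
  tr1 <- noiseless_truth(protocol_scale = c(A = 1, B = 0.9))
  gen1 <- generate_experiment(tr1, seed = 33)
  em1 <- truth_error_model(default_truth(
    protocol_scale = c(A = 1, B = 0.9),
    background_rsd_percent = c(A = 5, B = 5)))
  sim1 <- run_simulation(gen1$measurements, tr1$layout, em1,
                         cycles = 2000, seed = 34)
  cmp1 <- compare_protocols(sim1, "A", "B")
  expect_true(cmp1$significant)
  expect_gt(cmp1$mean_diff, 0)
  expect_gt(cmp1$sign_agreement, 0.99)

  expect_error(compare_protocols(sim1, "A", "Z"), "not simulated")
  expect_error(compare_protocols(sim1$samples, "A", "B"), "dose_sim")
})

test_that("sharing the calibration draw shrinks paired-difference error", {
  tr <- default_truth()
  gen <- generate_experiment(tr, seed = 41)
  # make the calibration component dominant enough to measure cleanly
  em <- truth_error_model(tr, cf_error_mode = "direct")
  shared <- run_simulation(gen$measurements, tr$layout, em, cycles = 5000,
                           seed = 42, shared_cf = TRUE)
  indep <- run_simulation(gen$measurements, tr$layout, em, cycles = 5000,
                          seed = 42, shared_cf = FALSE)
  for (nm in names(shared$comparisons)) {
    expect_lte(shared$comparisons[[nm]]$sd_diff,
               indep$comparisons[[nm]]$sd_diff)
  }
  # per-protocol marginal errors are comparable in the two modes
  expect_equal(shared$summaries$rsd_percent, indep$summaries$rsd_percent,
               tolerance = 0.15)
})

test_that("simulation surface: summaries, printing, plotting", {
  tr <- default_truth()
  gen <- generate_experiment(tr, seed = 51)
  em <- truth_error_model(tr)
  sim <- run_simulation(gen$measurements, tr$layout, em, cycles = 400,
                        seed = 52)
  expect_equal(nrow(sim$samples), 400)
  expect_equal(colnames(sim$samples), tr$protocols)
  expect_equal(sim$summaries$rsd_percent,
               100 * sim$summaries$sd / sim$summaries$mean)
  expect_true(all(sim$summaries$ci_lower <= sim$summaries$ci_upper))
  expect_length(sim$comparisons, choose(4, 2))

  expect_output(print(sim), "Monte Carlo dose simulation")
  expect_output(print(summary(sim)), "Pairwise")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sim))
  expect_silent(plot(sim, type = "hist"))

  # the simulate() verb on a bundled experiment gives the same run
  de <- dose_experiment(gen$measurements, tr$layout, em)
  expect_output(print(de), "Random-error model")
  sim2 <- simulate(de, nsim = 400, seed = 52)
  expect_identical(sim2$samples, sim$samples)
})
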