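test_that("trace constructor validates monotone time and flags gaps", {
  expect_error(frequency_trace(c(0, 0.2, 0.1), c(1, 2, 3)),
               class = "pm_invalid_input")
  expect_warning(
    tr <- frequency_trace(c(seq(0, 1, by = 0.1), 3), rep(474, 12)),
    "gap"
  )
  expect_equal(nrow(attr(tr, "gaps")), 1)
})

test_that("low-pass filter preserves DC, kills high frequencies, shifts no peaks", {
  t <- seq(0, 20, by = 0.002)
  flat <- frequency_trace(t, rep(474.25, length(t)))
  out <- lowpass(flat, cutoff_hz = 2.5)
  expect_equal(out$frequency_hz, flat$frequency_hz, tolerance = 1e-9)

  # 50 Hz sinusoid far above a 2.5 Hz cutoff: attenuated by > 40 dB.
  sine <- frequency_trace(t, 474 + 0.5 * sin(2 * pi * 50 * t))
  fs <- lowpass(sine, cutoff_hz = 2.5)
  core <- fs$frequency_hz[t > 2 & t < 18]
  expect_lt(sd(core) / sd(0.5 * sin(2 * pi * 50 * t)), 0.01)

  # Zero-phase: a noiseless transit's extremum time is unchanged.
  sens <- quiet_sensor(); pump <- pump_schedule()
  sched <- dissolution_schedule(180, tibble::tibble(duration_min = 10,
                                                    rate_ug_min = 0))
  tr <- simulate_experiment(sens, pump, sched, duration_min = 0.5, seed = 1)
  fl <- lowpass(tr, pump = pump)
  # Compare within one lobe of the first transit (depths tie elsewhere).
  w <- tr$time_s > 4.0 & tr$time_s < 5.0
  expect_lt(abs(tr$time_s[w][which.min(tr$frequency_hz[w])] -
                  fl$time_s[w][which.min(fl$frequency_hz[w])]),
            1.5 * attr(tr, "sample_interval_s"))

  expect_error(lowpass(flat, cutoff_hz = 300), class = "pm_invalid_input")
  expect_error(lowpass(flat, cutoff_hz = -1), class = "pm_invalid_input")
})

test_that("baseline estimator tracks flat traces and slow drift despite peaks", {
  t <- seq(0, 120, by = 0.01)
  flat <- frequency_trace(t, rep(474.25, length(t)))
  expect_equal(estimate_baseline(flat)$baseline_hz, flat$frequency_hz)

  # Drift-only trace: recovered baseline slope within 1% of the true drift.
  drift_hz_per_s <- 0.1 / 3600
  dr <- frequency_trace(t, 474.25 + drift_hz_per_s * t)
  bl <- estimate_baseline(dr)
  core <- bl[bl$time_s > 20 & bl$time_s < 100, ]
  slope <- coef(lm(baseline_hz ~ time_s, data = core))[2]
  expect_equal(unname(slope), drift_hz_per_s, tolerance = 0.01)

  # With transit peaks present the baseline stays near truth everywhere.
  sens <- sensor_model(noise_sd_hz = 0.001)
  pump <- pump_schedule()
  sched <- dissolution_schedule(180, tibble::tibble(duration_min = 1e4,
                                                    rate_ug_min = 0))
  tr <- simulate_experiment(sens, pump, sched, duration_min = 5, seed = 2)
  bl2 <- estimate_baseline(lowpass(tr, pump = pump))
  expect_lt(max(abs(bl2$baseline_hz - 474.25)), 3 * sens$noise_sd_hz)
})

test_that("transit detection finds every pair, flags broken ones, keeps signs", {
  sens <- quiet_sensor(); pump <- pump_schedule()
  sched <- fig1d_schedule()
  tr <- simulate_experiment(sens, pump, sched, duration_min = 5, seed = 1)
  fl <- estimate_baseline(lowpass(tr, pump = pump))
  pairs <- detect_transits(fl, pump)
  expect_equal(nrow(pairs), 30)
  expect_true(all(pairs$flags == ""))
  # Denser-than-fluid pellet: downward peaks, negative mean heights.
  expect_true(all(pairs$mean_height_hz < 0))
  # Pair extrema are half a transit apart.
  expect_equal(pairs$t2_s - pairs$t1_s,
               rep(pump$transit_duration_s / 2, 30), tolerance = 0.05)

  # No pellet, no pairs.
  none <- simulate_experiment(
    sens, pump,
    dissolution_schedule(0, tibble::tibble(duration_min = 10, rate_ug_min = 0)),
    duration_min = 2, seed = 1
  )
  expect_equal(nrow(detect_transits(estimate_baseline(lowpass(none, pump = pump)),
                                    pump)), 0)

  # Erase one lobe of one transit: that transit is flagged singleton-peak.
  broken <- tr
  lobe <- broken$time_s >= 14 & broken$time_s <= 15
  broken$frequency_hz[lobe] <- 474.25
  flb <- estimate_baseline(lowpass(broken, pump = pump))
  pb <- detect_transits(flb, pump)
  expect_equal(sum(grepl("singleton-peak", pb$flags)), 1)
  expect_equal(nrow(pb), 30)
})

test_that("mass series carries calibrated masses, resolution and flags policy", {
  sens <- quiet_sensor(); pump <- pump_schedule()
  sched <- dissolution_schedule(180, tibble::tibble(duration_min = 10,
                                                    rate_ug_min = 0))
  tr <- simulate_experiment(sens, pump, sched, duration_min = 2, seed = 1)
  pairs <- detect_transits(estimate_baseline(lowpass(tr, pump = pump)), pump)
  ms <- to_mass_series(pairs, ref_cal())
  expect_s3_class(ms, "mass_series")
  expect_equal(ms$mass_ug, rep(180, nrow(ms)), tolerance = 5e-3)
  expect_equal(ms$uncertainty_ug, rep(0.7, nrow(ms)))
  expect_equal(ms$time_min, pairs$time_s / 60)

  # Empty pairs give an empty series; singletons are dropped by default.
  empty <- detect_transits(
    estimate_baseline(frequency_trace(seq(0, 1, 0.002),
                                      rep(474.25, 501))), pump
  )
  expect_equal(nrow(to_mass_series(empty, ref_cal())), 0)
})

test_that("mean of many noisy constant-mass measurements converges to truth", {
  sens <- sensor_model(noise_sd_hz = 0.006)
  pump <- pump_schedule()
  sched <- dissolution_schedule(50, tibble::tibble(duration_min = 1e4,
                                                   rate_ug_min = 0))
  tr <- simulate_experiment(sens, pump, sched, duration_min = 40, seed = 11)
  pairs <- detect_transits(estimate_baseline(lowpass(tr, pump = pump)), pump)
  ms <- to_mass_series(pairs, ref_cal())
  expect_gte(nrow(ms), 230)
  expect_lt(abs(mean(ms$mass_ug) - 50),
            3 * sd(ms$mass_ug) / sqrt(nrow(ms)) + 0.05)
})
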