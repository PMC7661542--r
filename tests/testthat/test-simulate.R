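test_that("mode-shape weight has nodes at the bases/midpoint and maxima at the tips", {
  expect_equal(mode_weight(c(0, 0.5, 1)), c(0, 0, 0))
  expect_equal(mode_weight(c(0.25, 0.75)), c(1, 1))
  expect_equal(mode_weight(0.125), 0.5)
  expect_error(mode_weight(1.2), class = "pm_invalid_input")
  expect_error(mode_weight(-0.01), class = "pm_invalid_input")
})

test_that("scheduled trajectories evaluate piecewise with jumps, tail rate and floor", {
  sched <- fig1d_schedule()
  expect_equal(pellet_mass_at(0, sched), 170)
  expect_equal(pellet_mass_at(6, sched), 137)
  # After the declared phases the final rate continues to the ghost floor.
  expect_equal(pellet_mass_at(40, sched), 15)
  # The jump ramps linearly across its 10 s span: half applied after 5 s.
  expect_equal(pellet_mass_at(7 + 1 / 12, sched),
               pellet_mass_at(7, sched) - 25 - 2.5 / 12)
  # Monotone non-increasing when all rates and jumps are non-positive.
  t <- seq(0, 45, by = 0.05)
  expect_true(all(diff(pellet_mass_at(t, sched)) <= 1e-12))
  expect_error(pellet_mass_at(-1, sched), class = "pm_invalid_input")
})

test_that("simulated transits have closed-form extremum depth and exact counts", {
  sens <- quiet_sensor()
  pump <- pump_schedule()
  flat <- dissolution_schedule(180, tibble::tibble(duration_min = 1e5,
                                                  rate_ug_min = 0))
  tr <- simulate_experiment(sens, pump, flat, duration_min = 2, seed = 1)
  # 180 ug at responsivity 1/K (K = 1.8e-3 g/Hz) dips 0.1 Hz below baseline.
  expect_equal(min(tr$frequency_hz), 474.25 - 0.1, tolerance = 1e-6)
  expect_equal(max(tr$frequency_hz), 474.25)

  # Massless pellet: flat trace at the base frequency (plus drift if any).
  empty <- dissolution_schedule(0, tibble::tibble(duration_min = 1e5,
                                                  rate_ug_min = 0))
  tr0 <- simulate_experiment(sens, pump, empty, duration_min = 1, seed = 1)
  expect_equal(unique(tr0$frequency_hz), 474.25)
  drift <- sensor_model(noise_sd_hz = 0, drift_rate_hz_per_hr = 0.5)
  trd <- simulate_experiment(drift, pump, empty, duration_min = 1, seed = 1)
  expect_equal(trd$frequency_hz, 474.25 + 0.5 * trd$time_s / 3600)

  # Transit count = floor(duration / reversal period).
  for (dur in c(1, 2.5, 5)) {
    tri <- simulate_experiment(sens, pump, flat, duration_min = dur, seed = 1)
    expect_equal(attr(tri, "metadata")$n_transits, floor(dur * 60 / 10))
  }
})

test_that("traces are deterministic given a seed and differ across seeds", {
  sens <- sensor_model(noise_sd_hz = 0.002)
  pump <- pump_schedule()
  sched <- dissolution_schedule(90, tibble::tibble(duration_min = 10,
                                                   rate_ug_min = -1))
  a <- simulate_experiment(sens, pump, sched, duration_min = 1, seed = 7)
  b <- simulate_experiment(sens, pump, sched, duration_min = 1, seed = 7)
  c <- simulate_experiment(sens, pump, sched, duration_min = 1, seed = 8)
  expect_identical(a$frequency_hz, b$frequency_hz)
  expect_false(identical(a$frequency_hz, c$frequency_hz))
  # Different seeds differ only in noise: means agree within 3 SE.
  se <- sens$noise_sd_hz / sqrt(nrow(a))
  expect_lt(abs(mean(a$frequency_hz) - mean(c$frequency_hz)), 3 * sqrt(2) * se)
})

test_that("density fixture means sit on the sensor's linear density response", {
  sens <- quiet_sensor()
  fx <- make_density_fixture(sens, hold_min = 0.05, seed = 1)
  expect_setequal(unique(fx$density_g_ml), c(1.00, 1.02, 1.04, 1.06, 1.08))
  means <- tapply(fx$frequency_hz, fx$density_g_ml, mean)
  rho <- as.numeric(names(means))
  expect_equal(as.numeric(means), 474.25 - 300 * (rho - 1), tolerance = 1e-12)
  # Seeded regeneration is identical.
  fx2 <- make_density_fixture(sensor_model(), hold_min = 0.05, seed = 5)
  fx3 <- make_density_fixture(sensor_model(), hold_min = 0.05, seed = 5)
  expect_identical(fx2, fx3)
})

test_that("bead fixture yields constant replicate heights at zero noise", {
  sens <- quiet_sensor()
  pump <- pump_schedule()
  tr <- make_bead_fixture(sens, pump, bead_buoyant_mass_ug = 90,
                          n_transits = 5, seed = 1)
  pairs <- detect_transits(estimate_baseline(lowpass(tr, pump = pump)), pump)
  expect_equal(nrow(pairs), 5)
  expect_lt(diff(range(pairs$mean_height_hz)), 1e-6)
  # A massless bead produces no detectable peaks.
  tr0 <- make_bead_fixture(sens, pump, bead_buoyant_mass_ug = 0,
                           n_transits = 3, seed = 1)
  expect_equal(nrow(detect_transits(estimate_baseline(lowpass(tr0, pump = pump)),
                                    pump)), 0)
  expect_error(make_bead_fixture(sens, pump, 90, n_transits = 1),
               class = "pm_insufficient_data")
})

test_that("invalid schedules are rejected", {
  expect_error(pump_schedule(10, 12), class = "pm_invalid_input")
  expect_error(dissolution_schedule(-1, tibble::tibble(duration_min = 1,
                                                       rate_ug_min = 0)),
               class = "pm_invalid_input")
  expect_error(
    dissolution_schedule(10, tibble::tibble(duration_min = -1, rate_ug_min = 0)),
    class = "pm_invalid_input"
  )
})
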