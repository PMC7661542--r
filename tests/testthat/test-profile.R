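test_that("jump detection reports sudden drops and ignores gentle slopes", {
  # Gentle monotone dissolution: no jumps.
  t <- seq(0, 30, by = 1 / 6)
  gentle <- make_series(t, 100 - 1.2 * t)
  expect_equal(nrow(detect_jumps(gentle, min_drop_ug = 5)), 0)

  # Two scheduled sudden losses are both found, in time order.
  sched <- dissolution_schedule(
    200,
    phases = tibble::tibble(duration_min = 40, rate_ug_min = -0.5),
    jumps = tibble::tibble(time_min = c(10, 25), dmass_ug = c(-40, -30),
                           span_s = c(10, 10))
  )
  ser <- make_series(t + 1 / 12, pellet_mass_at(t + 1 / 12, sched))
  jt <- detect_jumps(ser, min_drop_ug = 10, max_span_s = 30)
  expect_equal(nrow(jt), 2)
  expect_true(all(diff(jt$time_min) > 0))
  expect_equal(jt$time_min, c(10, 25), tolerance = 0.3)
  expect_equal(jt$dmass_ug, c(-40, -30), tolerance = 0.15)

  expect_warning(detect_jumps(make_series(t, 100 - 1.2 * t, 10), min_drop_ug = 5),
                 "uncertainty")
})

test_that("segmentation recovers one- and two-phase dissolution rates", {
  t <- seq(0, 30, by = 1 / 6)
  withr::with_seed(21, {
    one <- make_series(t, 80 - 1.2 * t + rnorm(length(t), 0, 0.2))
  })
  seg1 <- segment_profile(one)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$rate_ug_min, -1.2, tolerance = 0.05 * 1.2)

  t2 <- seq(0, 35, by = 1 / 6)
  truth <- ifelse(t2 <= 30, 18 - 0.18 * t2, 18 - 0.18 * 30 - 1.5 * (t2 - 30))
  withr::with_seed(22, {
    two <- make_series(t2, truth + rnorm(length(t2), 0, 0.2))
  })
  seg2 <- segment_profile(two)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$rate_ug_min[1], -0.18, tolerance = 0.15 * 0.18)
  expect_equal(seg2$rate_ug_min[2], -1.5, tolerance = 0.15 * 1.5)
  expect_lt(abs(seg2$t_end_min[1] - 30), 1.5)
  # Segments partition the observed span contiguously.
  expect_equal(seg2$t_start_min[2], seg2$t_end_min[1])
  expect_equal(seg2$t_start_min[1], min(t2))
  expect_equal(seg2$t_end_min[2], max(t2))

  # Flat series: a single segment with rate indistinguishable from zero.
  withr::with_seed(23, {
    flat <- make_series(seq(0, 40, by = 1 / 6), 30 + rnorm(241, 0, 0.2))
  })
  segf <- segment_profile(flat)
  expect_equal(nrow(segf), 1)
  expect_lt(abs(segf$rate_ug_min), 2 * 0.2 / sqrt(241))
  expect_error(segment_profile(make_series(1:2, c(1, 2))),
               class = "pm_insufficient_data")
  expect_warning(segment_profile(make_series(seq_len(8), 8:1), max_segments = 6),
                 "reduced")
})

test_that("segmentation is invariant to time shifts and mass rescaling", {
  t <- seq(0, 35, by = 1 / 6)
  truth <- ifelse(t <= 20, 60 - 0.5 * t, 60 - 0.5 * 20 - 3 * (t - 20))
  withr::with_seed(31, noise <- rnorm(length(t), 0, 0.2))
  base <- segment_profile(make_series(t, truth + noise))
  shifted <- segment_profile(make_series(t + 120, truth + noise))
  scaled <- segment_profile(make_series(t, 10 * (truth + noise)))
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(shifted$t_end_min[1] - 120, base$t_end_min[1], tolerance = 1e-9)
  expect_equal(shifted$rate_ug_min, base$rate_ug_min, tolerance = 1e-9)
  expect_equal(nrow(scaled), nrow(base))
  expect_equal(scaled$rate_ug_min, 10 * base$rate_ug_min, tolerance = 1e-9)
})

test_that("recovered phase count matches the scheduled count across replicates", {
  # Two-phase schedules patterned on commercial pellet narratives.
  cases <- list(c(-0.18, -1.5, 18), c(-0.20, -4.4, 25), c(-0.10, -0.40, 7))
  hits <- 0L
  trials <- 0L
  for (ci in seq_along(cases)) {
    rates <- cases[[ci]][1:2]
    m0 <- cases[[ci]][3]
    for (r in 1:10) {
      trials <- trials + 1L
      t <- seq(0, 30, by = 1 / 6)
      brk <- 10 + 10 * (r %% 3) / 2
      truth <- ifelse(t <= brk, m0 + rates[1] * t,
                      m0 + rates[1] * brk + rates[2] * (t - brk))
      truth <- pmax(truth, 0)
      keep <- truth > 0.5
      withr::with_seed(1000 + 100 * ci + r, {
        ser <- make_series(t[keep], truth[keep] + rnorm(sum(keep), 0, 0.2))
      })
      if (nrow(segment_profile(ser)) == 2) hits <- hits + 1L
    }
  }
  expect_gte(hits / trials, 0.9)
})

test_that("profile metrics capture start, ghost, onset and completion", {
  sched <- fig1d_schedule()
  ser <- sample_schedule(sched, 40, sigma_ug = 0.2, seed = 41)
  pr <- fit_dissolution_profile(ser, min_drop_ug = 15)
  g <- glance(pr)
  expect_equal(g$start_mass_ug, 170, tolerance = 0.01)
  expect_equal(g$ghost_mass_ug, 15, tolerance = 0.05)
  expect_equal(g$ghost_fraction_pct, 100 * 15 / 170, tolerance = 0.05)
  expect_equal(g$onset_time_min, 5, tolerance = 0.5)
  expect_true(is.na(g$completion_time_min))
  expect_equal(g$n_jumps, 1)
  expect_equal(tidy(pr), tibble::as_tibble(pr$segments))

  # A series that dissolves to nothing: ghost 0 and a completion time.
  t <- seq(0, 20, by = 1 / 6)
  gone <- make_series(t, pmax(40 - 4 * t, 0), uncertainty_ug = 0.01)
  prg <- fit_dissolution_profile(gone, min_drop_ug = 5,
                                 dissolved_threshold_ug = 1)
  expect_equal(prg$metrics$ghost_mass_ug, 0)
  expect_equal(prg$metrics$completion_time_min, 10, tolerance = 0.3)

  # A constant series: nothing dissolved, no onset, no completion.
  const <- make_series(t, rep(50, length(t)), uncertainty_ug = 0.01)
  prc <- fit_dissolution_profile(const, min_drop_ug = 5)
  expect_equal(prc$metrics$ghost_fraction_pct, 100)
  expect_true(is.na(prc$metrics$onset_time_min))
  expect_true(is.na(prc$metrics$completion_time_min))
})

test_that("refined jump magnitude is unbiased against the flanking trends", {
  sched <- fig1d_schedule()
  ser <- sample_schedule(sched, 40, sigma_ug = 0, seed = 1)
  ser$uncertainty_ug <- 0.1
  pr <- fit_dissolution_profile(ser, min_drop_ug = 15)
  expect_equal(nrow(pr$jumps), 1)
  expect_equal(abs(pr$jumps$dmass_ug), 50, tolerance = 0.02)
  expect_equal(pr$jumps$time_min, 7.1, tolerance = 0.3)
})

test_that("mass balance closes on scheduled trajectories", {
  for (s in list(
    list(sched = fig1d_schedule(), dur = 40, drop = 15),
    list(sched = dissolution_schedule(
      18, tibble::tibble(duration_min = c(30, 10), rate_ug_min = c(-0.18, -1.5))
    ), dur = 40, drop = 5)
  )) {
    ser <- sample_schedule(s$sched, s$dur, sigma_ug = 0.2, seed = 51)
    ser <- ser[ser$mass_ug > 0.8, ]
    pr <- fit_dissolution_profile(ser, min_drop_ug = s$drop,
                                  dissolved_threshold_ug = 2.1)
    mb <- mass_balance(pr)
    expect_lt(abs(mb$z), 3)
  }
})
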