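# Forward model: synthetic resonance-frequency traces and calibration
# fixtures, so every downstream stage can be tested against known truth.

#' Sensor forward-model parameters
#'
#' Describes a vibrating-tube sensor well enough to synthesise its raw
#' frequency output. The defaults mirror a glass-tube densitometer
#' resonating near 474.25 Hz when filled with water, sampled once per
#' oscillation period (about every 2 ms).
#'
#' @param base_frequency_hz Resonance frequency at the reference fluid
#'   density (Hz).
#' @param density_slope_hz_per_g_ml Baseline shift per unit fluid density
#'   (Hz per g/mL, negative).
#' @param responsivity_hz_per_g Peak depth per gram of buoyant mass at the
#'   tine tip (Hz/g, positive). Reciprocal of the point-mass calibration
#'   constant; the default pairs a 0.1 Hz peak with a 180 ug pellet.
#' @param noise_sd_hz SD of i.i.d. Gaussian noise added to every sample.
#' @param drift_rate_hz_per_hr Linear baseline drift.
#' @param sample_interval_s Sampling interval in seconds.
#' @param reference_density_g_ml Fluid density at which the baseline equals
#'   `base_frequency_hz`.
#' @return An object of class `sensor_model`.
#' @examples
#' sensor_model(noise_sd_hz = 0.001)
#' @export
sensor_model <- function(base_frequency_hz = 474.25,
                         density_slope_hz_per_g_ml = -300,
                         responsivity_hz_per_g = 1 / 1.8e-3,
                         noise_sd_hz = 0.001,
                         drift_rate_hz_per_hr = 0,
                         sample_interval_s = 0.002,
                         reference_density_g_ml = 1.000) {
  check_number(base_frequency_hz, "base_frequency_hz", positive = TRUE)
  check_number(responsivity_hz_per_g, "responsivity_hz_per_g", positive = TRUE)
  check_number(noise_sd_hz, "noise_sd_hz", nonneg = TRUE)
  check_number(sample_interval_s, "sample_interval_s", positive = TRUE)
  check_number(drift_rate_hz_per_hr, "drift_rate_hz_per_hr")
  if (density_slope_hz_per_g_ml >= 0) {
    stop_invalid("`density_slope_hz_per_g_ml` must be negative.")
  }
  structure(
    list(
      base_frequency_hz = base_frequency_hz,
      density_slope_hz_per_g_ml = density_slope_hz_per_g_ml,
      responsivity_hz_per_g = responsivity_hz_per_g,
      noise_sd_hz = noise_sd_hz,
      drift_rate_hz_per_hr = drift_rate_hz_per_hr,
      sample_interval_s = sample_interval_s,
      reference_density_g_ml = reference_density_g_ml
    ),
    class = "sensor_model"
  )
}

#' Pump flow-reversal schedule
#'
#' The peristaltic pump reverses flow direction on a fixed period, carrying
#' the pellet through the vibrating section once per reversal.
#'
#' @param reversal_period_s Seconds between flow reversals.
#' @param transit_duration_s Seconds the pellet spends traversing the
#'   vibrating section (inlet base to outlet base); must not exceed
#'   `reversal_period_s`.
#' @param phase_offset_s Transit start time within each reversal window;
#'   defaults to centring the transit in the window.
#' @return An object of class `pump_schedule`.
#' @export
pump_schedule <- function(reversal_period_s = 10, transit_duration_s = 2,
                          phase_offset_s = NULL) {
  check_number(reversal_period_s, "reversal_period_s", positive = TRUE)
  check_number(transit_duration_s, "transit_duration_s", positive = TRUE)
  if (transit_duration_s > reversal_period_s) {
    stop_invalid("`transit_duration_s` must be <= `reversal_period_s`.")
  }
  if (is.null(phase_offset_s)) {
    phase_offset_s <- (reversal_period_s - transit_duration_s) / 2
  }
  check_number(phase_offset_s, "phase_offset_s", nonneg = TRUE)
  if (phase_offset_s + transit_duration_s > reversal_period_s) {
    stop_invalid("Transit must fit inside one reversal window.")
  }
  structure(
    list(
      reversal_period_s = reversal_period_s,
      transit_duration_s = transit_duration_s,
      phase_offset_s = phase_offset_s
    ),
    class = "pump_schedule"
  )
}

#' Scheduled buoyant-mass trajectory of a dissolving pellet
#'
#' Describes the ground-truth trajectory as ordered constant-rate phases
#' plus optional abrupt jump events, with a floor representing the insoluble
#' residue ("ghost"). After the last declared phase the final rate continues
#' until the floor is reached, after which the mass holds at the floor; the
#' trajectory is clipped at the floor throughout. Jumps are ramped linearly
#' over `span_s` seconds (0 = instantaneous step).
#'
#' @param initial_mass_ug Buoyant mass at t = 0 (ug).
#' @param phases Data frame with columns `duration_min` and `rate_ug_min`,
#'   applied in order from t = 0.
#' @param jumps Optional data frame with columns `time_min`, `dmass_ug`
#'   (signed; negative = sudden loss) and optionally `span_s` (default 10).
#' @param floor_ug Lower clip for the trajectory (ug, >= 0).
#' @return An object of class `dissolution_schedule`.
#' @examples
#' # A delayed-release pellet: flat, fast loss, sudden 50 ug drop, slow tail.
#' dissolution_schedule(
#'   170,
#'   phases = data.frame(duration_min = c(5, 2, 12),
#'                       rate_ug_min = c(0, -33, -2.5)),
#'   jumps = data.frame(time_min = 7, dmass_ug = -50, span_s = 10),
#'   floor_ug = 15
#' )
#' @export
dissolution_schedule <- function(initial_mass_ug, phases,
                                 jumps = NULL, floor_ug = 0) {
  check_number(initial_mass_ug, "initial_mass_ug", nonneg = TRUE)
  check_number(floor_ug, "floor_ug", nonneg = TRUE)
  phases <- as_tibble(phases)
  if (!all(c("duration_min", "rate_ug_min") %in% names(phases)) ||
      nrow(phases) == 0) {
    stop_invalid("`phases` needs columns `duration_min` and `rate_ug_min` and at least one row.")
  }
  if (any(phases$duration_min <= 0)) stop_invalid("Phase durations must be > 0.")
  if (is.null(jumps)) {
    jumps <- tibble(time_min = numeric(), dmass_ug = numeric(), span_s = numeric())
  } else {
    jumps <- as_tibble(jumps)
    if (!all(c("time_min", "dmass_ug") %in% names(jumps))) {
      stop_invalid("`jumps` needs columns `time_min` and `dmass_ug`.")
    }
    if (!"span_s" %in% names(jumps)) jumps$span_s <- 10
    jumps <- dplyr::arrange(jumps, .data$time_min)
  }
  structure(
    list(
      initial_mass_ug = initial_mass_ug,
      phases = phases,
      jumps = jumps,
      floor_ug = floor_ug
    ),
    class = "dissolution_schedule"
  )
}

#' Vibrational mode-shape weight along the tube path
#'
#' The tube's vibrational amplitude is zero at its mounted bases and at the
#' midpoint between the tines, and largest at the two tine tips, so a point
#' mass affects the resonance frequency most at the tips. The path
#' coordinate `s` runs 0 (inlet base) through 0.25 (first tip), 0.5
#' (midpoint), 0.75 (second tip) to 1 (outlet base); the weight is
#' \eqn{w(s) = \sin^2(2\pi s)}.
#'
#' @param s Path coordinate(s) in \[0, 1\].
#' @return Weight(s) in \[0, 1\].
#' @examples
#' mode_weight(c(0, 0.25, 0.5, 0.75, 1))
#' @export
mode_weight <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0 | s > 1)) {
    stop_invalid("`s` must lie in [0, 1].")
  }
  sin(2 * pi * s)^2
}

#' Evaluate a dissolution schedule at given times
#'
#' Piecewise-linear-with-ramped-jumps evaluation of the scheduled buoyant
#' mass, clipped at the schedule floor. See [dissolution_schedule()] for the
#' trajectory semantics.
#'
#' @param t_min Time(s) in minutes, >= 0.
#' @param sched A [dissolution_schedule()].
#' @return Buoyant mass(es) in micrograms.
#' @examples
#' sched <- dissolution_schedule(100, data.frame(duration_min = 10,
#'                                               rate_ug_min = -5))
#' pellet_mass_at(c(0, 10, 30), sched)
#' @export
pellet_mass_at <- function(t_min, sched) {
  stopifnot(inherits(sched, "dissolution_schedule"))
  if (any(t_min < 0)) stop_invalid("`t_min` must be >= 0.")
  ph <- sched$phases
  starts <- cumsum(c(0, ph$duration_min))
  n_ph <- nrow(ph)
  # Mass at each phase start, before jumps.
  m_at <- sched$initial_mass_ug +
    cumsum(c(0, ph$rate_ug_min * ph$duration_min))
  base <- numeric(length(t_min))
  for (i in seq_along(t_min)) {
    t <- t_min[i]
    if (t >= starts[n_ph + 1]) {
      # Past the declared phases: final rate continues (floor clip below).
      base[i] <- m_at[n_ph + 1] + ph$rate_ug_min[n_ph] * (t - starts[n_ph + 1])
    } else {
      k <- findInterval(t, starts, rightmost.closed = FALSE)
      base[i] <- m_at[k] + ph$rate_ug_min[k] * (t - starts[k])
    }
  }
  if (nrow(sched$jumps) > 0) {
    for (j in seq_len(nrow(sched$jumps))) {
      t0 <- sched$jumps$time_min[j]
      span_min <- sched$jumps$span_s[j] / 60
      dm <- sched$jumps$dmass_ug[j]
      frac <- if (span_min > 0) {
        pmin(1, pmax(0, (t_min - t0) / span_min))
      } else {
        as.numeric(t_min >= t0)
      }
      base <- base + dm * frac
    }
  }
  pmax(base, sched$floor_ug)
}

#' Simulate a full single-pellet dissolution experiment
#'
#' Generates the raw resonance-frequency trace of a pellet repeatedly pumped
#' back and forth through the sensor while its mass follows a dissolution
#' schedule. Each reversal window contains one transit; the pellet's path
#' coordinate advances linearly over the transit, so each transit produces
#' two extrema (one per tine tip) of equal expected depth
#' `responsivity * m_b(t)` (in grams). Gaussian noise and linear drift are
#' added on top; the trace is deterministic given `seed`.
#'
#' @param sensor A [sensor_model()].
#' @param pump A [pump_schedule()].
#' @param sched A [dissolution_schedule()].
#' @param duration_min Experiment duration in minutes.
#' @param seed Integer seed for the noise.
#' @param fl Optional [fluid()]; a density different from the sensor's
#'   reference shifts the baseline by `density_slope * (rho - reference)`.
#' @return A `frequency_trace` tibble with columns `time_s`, `frequency_hz`
#'   (attributes: `sample_interval_s`, `metadata`).
#' @examples
#' tr <- simulate_experiment(
#'   sensor_model(noise_sd_hz = 0), pump_schedule(),
#'   dissolution_schedule(100, data.frame(duration_min = 5, rate_ug_min = 0)),
#'   duration_min = 1, seed = 1
#' )
#' @export
simulate_experiment <- function(sensor, pump, sched, duration_min, seed = 1L,
                                fl = NULL) {
  stopifnot(
    inherits(sensor, "sensor_model"), inherits(pump, "pump_schedule"),
    inherits(sched, "dissolution_schedule")
  )
  check_number(duration_min, "duration_min", positive = TRUE)
  dt <- sensor$sample_interval_s
  duration_s <- duration_min * 60
  n <- floor(duration_s / dt)
  time_s <- (seq_len(n) - 1) * dt

  fluid_density <- if (is.null(fl)) sensor$reference_density_g_ml else fl$density_g_ml
  baseline <- sensor$base_frequency_hz +
    sensor$density_slope_hz_per_g_ml * (fluid_density - sensor$reference_density_g_ml) +
    sensor$drift_rate_hz_per_hr * time_s / 3600

  f <- baseline
  n_transits <- floor(duration_s / pump$reversal_period_s)
  if (n_transits > 0) {
    for (k in seq_len(n_transits) - 1L) {
      t0 <- k * pump$reversal_period_s + pump$phase_offset_s
      i0 <- max(1L, ceiling(t0 / dt) + 1L)
      i1 <- min(n, floor((t0 + pump$transit_duration_s) / dt) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      s <- (time_s[idx] - t0) / pump$transit_duration_s
      mb_ug <- pellet_mass_at(time_s[idx] / 60, sched)
      f[idx] <- f[idx] -
        sensor$responsivity_hz_per_g * (mb_ug / MICROGRAMS_PER_GRAM) * mode_weight(s)
    }
  }
  if (sensor$noise_sd_hz > 0) {
    noise <- withr::with_seed(seed, rnorm(n, 0, sensor$noise_sd_hz))
    f <- f + noise
  }
  frequency_trace(
    time_s, f,
    sample_interval_s = dt,
    metadata = list(
      fluid = if (is.null(fl)) "" else fl$label,
      fluid_density_g_ml = fluid_density,
      seed = seed,
      n_transits = n_transits
    )
  )
}

#' Simulate the bulk-density calibration fixture
#'
#' Emulates filling the sensor with a series of salt solutions of precisely
#' known densities and recording the resonance frequency for a hold period
#' at each: the mean frequency at each density lies on the sensor's linear
#' density response (plus noise).
#'
#' @param sensor A [sensor_model()].
#' @param densities_g_ml Known fluid densities (g/mL).
#' @param hold_min Recording time per density, minutes.
#' @param seed Integer seed.
#' @return A tibble with columns `density_g_ml`, `time_s`, `frequency_hz`,
#'   one hold block per density.
#' @export
make_density_fixture <- function(sensor,
                                 densities_g_ml = c(1.00, 1.02, 1.04, 1.06, 1.08),
                                 hold_min = 10, seed = 1L) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (length(densities_g_ml) < 2) stop_insufficient("Need at least two densities.")
  check_number(hold_min, "hold_min", positive = TRUE)
  dt <- sensor$sample_interval_s
  n <- floor(hold_min * 60 / dt)
  time_s <- (seq_len(n) - 1) * dt
  blocks <- withr::with_seed(seed, {
    purrr::map(densities_g_ml, function(rho) {
      f <- sensor$base_frequency_hz +
        sensor$density_slope_hz_per_g_ml * (rho - sensor$reference_density_g_ml)
      noise <- if (sensor$noise_sd_hz > 0) rnorm(n, 0, sensor$noise_sd_hz) else 0
      tibble(density_g_ml = rho, time_s = time_s, frequency_hz = f + noise)
    })
  })
  dplyr::bind_rows(blocks)
}

#' Simulate the point-mass calibration bead fixture
#'
#' A microbead of known mass and density is passed through the sensor
#' repeatedly at constant buoyant mass; the resulting trace is used to fit
#' the point-mass calibration constant and (from replicate scatter) the mass
#' resolution.
#'
#' @param sensor A [sensor_model()].
#' @param pump A [pump_schedule()].
#' @param bead_buoyant_mass_ug Bead buoyant mass (ug).
#' @param n_transits Number of bead passages (>= 2).
#' @param seed Integer seed.
#' @return A `frequency_trace` tibble.
#' @export
make_bead_fixture <- function(sensor, pump, bead_buoyant_mass_ug,
                              n_transits = 50, seed = 1L) {
  if (n_transits < 2) stop_insufficient("Need at least two bead transits.")
  check_number(bead_buoyant_mass_ug, "bead_buoyant_mass_ug", nonneg = TRUE)
  sched <- dissolution_schedule(
    bead_buoyant_mass_ug,
    phases = tibble(duration_min = 1e6, rate_ug_min = 0)
  )
  simulate_experiment(
    sensor, pump, sched,
    duration_min = n_transits * pump$reversal_period_s / 60,
    seed = seed
  )
}
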