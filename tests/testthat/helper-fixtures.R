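# Shared fixtures, built in code.

# Mass series constructor used throughout the profile tests.
make_series <- function(time_min, mass_ug, uncertainty_ug = 0.2,
                        detection_floor_ug = NULL) {
  out <- tibble::new_tibble(
    list(
      time_min = time_min, mass_ug = mass_ug,
      uncertainty_ug = rep_len(uncertainty_ug, length(time_min))
    ),
    nrow = length(time_min), class = "mass_series"
  )
  if (!is.null(detection_floor_ug)) {
    attr(out, "detection_floor_ug") <- detection_floor_ug
  }
  out
}

# The delayed-release pellet narrative used as the reference trajectory:
# 170 ug start, flat 5 min, -33 ug/min for 2 min, sudden -50 ug at 7 min
# within 10 s, then -2.5 ug/min down to a 15 ug insoluble ghost.
fig1d_schedule <- function() {
  dissolution_schedule(
    170,
    phases = tibble::tibble(duration_min = c(5, 2, 12),
                            rate_ug_min = c(0, -33, -2.5)),
    jumps = tibble::tibble(time_min = 7, dmass_ug = -50, span_s = 10),
    floor_ug = 15
  )
}

quiet_sensor <- function(...) sensor_model(noise_sd_hz = 0, ...)

ref_cal <- function() point_mass_calibration(1.8e-3, resolution_g = 700e-9)

# Sample a schedule's true trajectory at the pump cadence and add
# measurement noise, emulating a calibrated mass series without running the
# full trace pipeline.
sample_schedule <- function(sched, duration_min, sigma_ug = 0.2,
                            dt_min = 10 / 60, seed = 1) {
  t <- seq(dt_min / 2, duration_min, by = dt_min)
  m <- pellet_mass_at(t, sched)
  noise <- withr::with_seed(seed, rnorm(length(t), 0, sigma_ug))
  make_series(t, m + noise, uncertainty_ug = max(sigma_ug, 1e-6))
}
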