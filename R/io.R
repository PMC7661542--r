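# Readers, writers, run configuration and the end-to-end pipeline.

#' Read a raw frequency trace from CSV
#'
#' Expects the interchange header `time_s,frequency_hz`. Malformed rows and
#' non-monotone times are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @return A `frequency_trace` tibble.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("No such file: %s", path))
  df <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(
      time_s = readr::col_double(), frequency_hz = readr::col_double()
    ),
    progress = FALSE
  ))
  if (!all(c("time_s", "frequency_hz") %in% names(df))) {
    stop_invalid("Trace CSV must have columns `time_s` and `frequency_hz`.")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_invalid(sprintf(
      "Malformed trace CSV: %d bad cell(s), first at line %d.",
      nrow(probs), probs$row[1] + 1L
    ))
  }
  if (anyNA(df$time_s) || anyNA(df$frequency_hz)) {
    bad <- which(is.na(df$time_s) | is.na(df$frequency_hz))[1]
    stop_invalid(sprintf("Non-numeric or missing cell at data row %d.", bad))
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1] + 1L
    stop_invalid(sprintf("Times are not strictly increasing at data row %d.", bad))
  }
  frequency_trace(df$time_s, df$frequency_hz)
}

#' Write a frequency trace to CSV
#'
#' Numbers are serialized at full double round-trip precision so that
#' write/read cycles are lossless.
#'
#' @param trace A `frequency_trace` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble(time_s = trace$time_s,
                          frequency_hz = trace$frequency_hz), path)
  invisible(path)
}

#' Read and write calibrated buoyant-mass series
#'
#' Interchange format: CSV with header `time_s,buoyant_mass_ug,uncertainty_ug`.
#'
#' @param path CSV path.
#' @return `read_mass_series()` returns a `mass_series` tibble (times in
#'   minutes); `write_mass_series()` returns `path` invisibly.
#' @export
read_mass_series <- function(path) {
  df <- readr::read_csv(path, col_types = "ddd", progress = FALSE)
  if (!all(c("time_s", "buoyant_mass_ug", "uncertainty_ug") %in% names(df))) {
    stop_invalid("Mass-series CSV must have columns `time_s,buoyant_mass_ug,uncertainty_ug`.")
  }
  out <- tibble(
    time_min = df$time_s / 60,
    mass_ug = df$buoyant_mass_ug,
    uncertainty_ug = df$uncertainty_ug
  )
  new_tibble(out, nrow = nrow(out), class = "mass_series")
}

#' @rdname read_mass_series
#' @param series A `mass_series` tibble.
#' @export
write_mass_series <- function(series, path) {
  readr::write_csv(tibble(
    time_s = series$time_min * 60,
    buoyant_mass_ug = series$mass_ug,
    uncertainty_ug = series$uncertainty_ug
  ), path)
  invisible(path)
}

#' Save and load sensor calibrations as JSON
#'
#' Serializes the bulk-density and point-mass calibration records to one
#' JSON file with keys `slope_hz_per_g_ml`, `reference_frequency_hz`,
#' `reference_density_g_ml`, `valid_range_g_ml`, `constant_g_per_hz`,
#' `resolution_g`, `n_replicates`.
#'
#' @param density_cal A [density_calibration()] (or NULL).
#' @param point_cal A [point_mass_calibration()] (or NULL).
#' @param path JSON file path.
#' @return `path` invisibly; `read_calibration()` returns a list with
#'   elements `density` and `point`.
#' @export
write_calibration <- function(density_cal = NULL, point_cal = NULL, path) {
  rec <- list()
  if (!is.null(density_cal)) {
    stopifnot(inherits(density_cal, "density_calibration"))
    rec$slope_hz_per_g_ml <- density_cal$slope_hz_per_g_ml
    rec$reference_frequency_hz <- density_cal$reference_frequency_hz
    rec$reference_density_g_ml <- density_cal$reference_density_g_ml
    rec$valid_range_g_ml <- density_cal$valid_range
  }
  if (!is.null(point_cal)) {
    stopifnot(inherits(point_cal, "point_mass_calibration"))
    rec$constant_g_per_hz <- point_cal$constant_g_per_hz
    rec$resolution_g <- point_cal$resolution_g
    rec$n_replicates <- point_cal$n_replicates
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(density = NULL, point = NULL)
  if (!is.null(rec$slope_hz_per_g_ml)) {
    out$density <- density_calibration(
      slope_hz_per_g_ml = rec$slope_hz_per_g_ml,
      reference_frequency_hz = rec$reference_frequency_hz,
      reference_density_g_ml = rec$reference_density_g_ml,
      valid_range = rec$valid_range_g_ml %||% c(1.00, 1.08)
    )
  }
  if (!is.null(rec$constant_g_per_hz)) {
    out$point <- point_mass_calibration(
      constant_g_per_hz = rec$constant_g_per_hz,
      resolution_g = rec$resolution_g %||% NA_real_,
      n_replicates = rec$n_replicates %||% NA_integer_
    )
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the trace-to-profile pipeline so a run is fully
#' reproducible from the configuration plus its seed. Round-trips losslessly
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param trace_path Input raw trace CSV.
#' @param calibration_path Calibration JSON (see [write_calibration()]).
#' @param output_dir Directory for pipeline artifacts.
#' @param cutoff_hz Low-pass filter cutoff (NULL = `5 / transit_duration`).
#' @param min_prominence_hz Peak detection threshold (NULL = automatic).
#' @param reversal_period_s,transit_duration_s Pump schedule.
#' @param min_drop_ug,max_span_s Jump detection settings (NULL = automatic).
#' @param penalty Segmentation penalty (NULL = automatic).
#' @param max_segments Maximum segments per inter-jump block.
#' @param dissolved_threshold_ug Dissolved threshold (NULL = 3x resolution).
#' @param seed Integer seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trace_path, calibration_path, output_dir,
                       cutoff_hz = NULL, min_prominence_hz = NULL,
                       reversal_period_s = 10, transit_duration_s = 2,
                       min_drop_ug = NULL, max_span_s = 30,
                       penalty = NULL, max_segments = 6,
                       dissolved_threshold_ug = NULL, seed = 1L) {
  cfg <- list(
    trace_path = trace_path, calibration_path = calibration_path,
    output_dir = output_dir, cutoff_hz = cutoff_hz,
    min_prominence_hz = min_prominence_hz,
    reversal_period_s = reversal_period_s,
    transit_duration_s = transit_duration_s,
    min_drop_ug = min_drop_ug, max_span_s = max_span_s,
    penalty = penalty, max_segments = max_segments,
    dissolved_threshold_ug = dissolved_threshold_ug,
    seed = as.integer(seed)
  )
  for (nm in c("reversal_period_s", "transit_duration_s", "max_span_s")) {
    check_number(cfg[[nm]], nm, positive = TRUE)
  }
  check_number(cfg$max_segments, "max_segments", positive = TRUE)
  for (nm in c("cutoff_hz", "min_prominence_hz", "min_drop_ug", "penalty",
               "dissolved_threshold_ug")) {
    if (!is.null(cfg[[nm]])) check_number(cfg[[nm]], nm, positive = TRUE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full trace-to-profile pipeline
#'
#' Reads the raw trace and calibration, low-pass filters, estimates the
#' baseline, detects transit peak pairs, converts them to a calibrated
#' buoyant-mass series, and fits the dissolution profile. Writes
#' `filtered_trace.csv`, `peak_table.csv`, `mass_series.csv`,
#' `profile.json` and `run_log.txt` into the output directory; identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The fitted `dissolution_profile` (invisibly the artifacts are on
#'   disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cal <- tryCatch(suppressWarnings(read_calibration(config$calibration_path)),
                  error = function(e) {
    stop_invalid(sprintf(
      "Cannot read calibration at '%s'; run fit_density_calibration()/fit_point_mass_calibration() (CLI: calibrate-density / calibrate-mass) first.",
      config$calibration_path
    ))
  })
  if (is.null(cal$point)) {
    stop_invalid("Calibration file has no point-mass record; run calibrate-mass first.")
  }
  trace <- read_trace(config$trace_path)
  if (nrow(trace) == 0) stop_insufficient("Empty trace: nothing to profile.")
  pump <- pump_schedule(config$reversal_period_s, config$transit_duration_s)
  filtered <- lowpass(trace, cutoff_hz = config$cutoff_hz, pump = pump)
  filtered <- estimate_baseline(filtered, window_s = 3 * pump$reversal_period_s)
  pairs <- detect_transits(filtered, pump,
                           min_prominence_hz = config$min_prominence_hz)
  if (nrow(pairs) == 0) stop_insufficient("No transit peaks detected; empty profile.")
  series <- to_mass_series(pairs, cal$point)
  profile <- fit_dissolution_profile(
    series,
    min_drop_ug = config$min_drop_ug, max_span_s = config$max_span_s,
    max_segments = config$max_segments, penalty = config$penalty,
    dissolved_threshold_ug = config$dissolved_threshold_ug
  )

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  write_trace(filtered, out("filtered_trace.csv"))
  readr::write_csv(
    tibble(
      transit_index = pairs$transit_index, time_s = pairs$time_s,
      mean_height_hz = pairs$mean_height_hz, baseline_hz = pairs$baseline_hz,
      flags = pairs$flags
    ),
    out("peak_table.csv")
  )
  write_mass_series(series, out("mass_series.csv"))
  jsonlite::write_json(
    list(
      segments = profile$segments, jumps = profile$jumps,
      metrics = profile$metrics
    ),
    out("profile.json"),
    auto_unbox = TRUE, digits = 10, na = "null", dataframe = "rows"
  )
  log_lines <- c(
    sprintf("pelletmass %s", as.character(utils::packageVersion("pelletmass"))),
    sprintf("seed: %d", config$seed),
    sprintf("trace: %s (%d samples)", config$trace_path, nrow(trace)),
    sprintf("transits detected: %d (flagged: %d)",
            nrow(pairs), sum(pairs$flags != "")),
    sprintf("mass points: %d", nrow(series)),
    sprintf("segments: %d, jumps: %d", nrow(profile$segments), nrow(profile$jumps)),
    "parameters:",
    vapply(
      setdiff(names(unclass(config)), character()),
      function(nm) sprintf("  %s: %s", nm,
                           paste(format(config[[nm]]), collapse = ", ")),
      character(1)
    )
  )
  writeLines(log_lines, out("run_log.txt"))
  profile
}

#' Built-in demonstration schedules
#'
#' Ground-truth dissolution schedules emulating the qualitative behaviours
#' of commercial proton-pump-inhibitor pellets in simulated intestinal
#' fluid (pH 7.0) and an enteric-coated control in simulated stomach fluid
#' (pH 2.0): a slow two-phase releaser, a delayed burst releaser with an
#' insoluble ghost, a mid-rate two-phase releaser, and a flat control.
#'
#' @return Named list of [dissolution_schedule()] objects with attributes
#'   `duration_min` and `fluid` on each element.
#' @export
demo_schedules <- function() {
  mk <- function(sched, duration_min, fluid_label) {
    attr(sched, "duration_min") <- duration_min
    attr(sched, "fluid") <- fluid_label
    sched
  }
  list(
    omeprazole_ph7 = mk(
      dissolution_schedule(
        18,
        phases = tibble(duration_min = c(30, 10), rate_ug_min = c(-0.18, -1.5)),
        floor_ug = 0
      ),
      40, "simulated intestinal fluid pH 7.0"
    ),
    lansoprazole_ph7 = mk(
      dissolution_schedule(
        170,
        phases = tibble(duration_min = c(10, 2), rate_ug_min = c(0, -77.5)),
        floor_ug = 15
      ),
      15, "simulated intestinal fluid pH 7.0"
    ),
    esomeprazole_ph7 = mk(
      dissolution_schedule(
        25,
        phases = tibble(duration_min = c(15, 10), rate_ug_min = c(-0.20, -4.4)),
        floor_ug = 0
      ),
      22, "simulated intestinal fluid pH 7.0"
    ),
    control_ph2 = mk(
      dissolution_schedule(
        30,
        phases = tibble(duration_min = 60, rate_ug_min = 0),
        floor_ug = 0
      ),
      45, "simulated stomach fluid pH 2.0"
    )
  )
}

#' Generate the packaged demonstration dataset
#'
#' Writes a complete synthetic stand-in for an instrument session: a
#' bulk-density calibration fixture, a reference-bead fixture, pellet
#' dissolution experiments for the [demo_schedules()] (three pH 7.0
#' releasers and a pH 2.0 flat control), and a `manifest.json` recording
#' every true parameter for testing.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; every trace is deterministic given it.
#' @param sensor A [sensor_model()]; defaults to 1 mHz sample noise.
#' @param pump A [pump_schedule()].
#' @param density_hold_min Hold time per density in the density fixture.
#' @return Invisibly, a list with the manifest and file paths.
#' @export
make_demo_dataset <- function(out_dir, seed = 1L,
                              sensor = sensor_model(),
                              pump = pump_schedule(),
                              density_hold_min = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  dens <- make_density_fixture(sensor, hold_min = density_hold_min, seed = seed)
  paths$density_fixture <- file.path(out_dir, "density_fixture.csv")
  readr::write_csv(dens, paths$density_fixture)

  bead_mb <- 90
  bead <- make_bead_fixture(sensor, pump, bead_buoyant_mass_ug = bead_mb,
                            n_transits = 50, seed = seed + 1L)
  paths$bead_fixture <- file.path(out_dir, "bead_fixture.csv")
  write_trace(bead, paths$bead_fixture)

  scheds <- demo_schedules()
  experiments <- list()
  for (i in seq_along(scheds)) {
    nm <- names(scheds)[i]
    sc <- scheds[[i]]
    tr <- simulate_experiment(
      sensor, pump, sc,
      duration_min = attr(sc, "duration_min"), seed = seed + 1L + i,
      fl = fluid(1.003, attr(sc, "fluid"))
    )
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_trace(tr, p)
    paths[[nm]] <- p
    experiments[[nm]] <- list(
      file = basename(p),
      fluid = attr(sc, "fluid"),
      duration_min = attr(sc, "duration_min"),
      initial_mass_ug = sc$initial_mass_ug,
      floor_ug = sc$floor_ug,
      phases = sc$phases,
      jumps = sc$jumps,
      seed = seed + 1L + i
    )
  }
  manifest <- list(
    seed = seed,
    sensor = unclass(sensor),
    pump = unclass(pump),
    bead_buoyant_mass_ug = bead_mb,
    density_fixture = list(
      file = basename(paths$density_fixture),
      densities_g_ml = unique(dens$density_g_ml),
      hold_min = density_hold_min
    ),
    experiments = experiments
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(manifest = manifest, paths = paths))
}
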