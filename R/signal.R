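# From raw frequency trace to per-transit peak-pair heights.

#' Construct a frequency trace
#'
#' A uniformly sampled resonance-frequency time series. Times must be
#' strictly increasing; sampling gaps larger than five sample intervals are
#' flagged (and reported via a warning) since the analysis assumes a near
#' uniform grid.
#'
#' @param time_s Sample times (s), strictly increasing.
#' @param frequency_hz Resonance frequency (Hz), same length.
#' @param sample_interval_s Nominal sampling interval; inferred from the
#'   median time step when NULL.
#' @param metadata Named list (fluid label, acquisition notes, seed, ...).
#' @return A tibble of class `frequency_trace` with columns `time_s`,
#'   `frequency_hz`; attributes `sample_interval_s`, `metadata`, `gaps`
#'   (tibble of flagged gaps).
#' @export
frequency_trace <- function(time_s, frequency_hz, sample_interval_s = NULL,
                            metadata = list()) {
  if (length(time_s) != length(frequency_hz)) {
    stop_invalid("`time_s` and `frequency_hz` must have equal length.")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop_invalid(sprintf("Times must be strictly increasing (first violation at row %d).", bad))
  }
  if (is.null(sample_interval_s)) {
    sample_interval_s <- if (length(time_s) > 1) median(diff(time_s)) else NA_real_
  }
  gaps <- tibble(row = integer(), time_s = numeric(), gap_s = numeric())
  if (length(time_s) > 1 && is.finite(sample_interval_s)) {
    dts <- diff(time_s)
    big <- which(dts > 5 * sample_interval_s)
    if (length(big) > 0) {
      gaps <- tibble(row = big + 1L, time_s = time_s[big + 1L], gap_s = dts[big])
      warn(sprintf("%d sampling gap(s) exceed 5x the sample interval.", length(big)))
    }
  }
  out <- new_tibble(
    list(time_s = as.numeric(time_s), frequency_hz = as.numeric(frequency_hz)),
    nrow = length(time_s), class = "frequency_trace"
  )
  attr(out, "sample_interval_s") <- sample_interval_s
  attr(out, "metadata") <- metadata
  attr(out, "gaps") <- gaps
  out
}

trace_interval <- function(trace) {
  dt <- attr(trace, "sample_interval_s")
  if (is.null(dt) || !is.finite(dt)) dt <- median(diff(trace$time_s))
  dt
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at the trace's nominal sample
#' interval. Used before filtering when sampling gaps were flagged.
#'
#' @param trace A `frequency_trace` (or tibble with `time_s`, `frequency_hz`).
#' @return A `frequency_trace` on a uniform grid.
#' @export
resample_uniform <- function(trace) {
  dt <- trace_interval(trace)
  grid <- seq(trace$time_s[1], trace$time_s[nrow(trace)], by = dt)
  f <- approx(trace$time_s, trace$frequency_hz, xout = grid)$y
  frequency_trace(grid, f, sample_interval_s = dt,
                  metadata = attr(trace, "metadata") %||% list())
}

#' Zero-phase low-pass filter a frequency trace
#'
#' Applies a 4th-order Butterworth low-pass forward and backward
#' (zero-phase, so peak times are not shifted). The trace mean is removed
#' before filtering and restored afterwards, and the series is padded by
#' reflection, so the DC gain is exactly 1 and constant traces pass through
#' unchanged.
#'
#' @param trace A `frequency_trace` tibble.
#' @param cutoff_hz Cutoff frequency; must satisfy 0 < cutoff < Nyquist.
#'   Default `5 / transit_duration` when `pump` is supplied, else 2.5 Hz.
#' @param pump Optional [pump_schedule()] used for the default cutoff.
#' @return The filtered trace (same shape and class; attribute
#'   `lowpass_cutoff_hz` records the cutoff).
#' @export
lowpass <- function(trace, cutoff_hz = NULL, pump = NULL) {
  dt <- trace_interval(trace)
  nyquist <- 1 / (2 * dt)
  if (is.null(cutoff_hz)) {
    cutoff_hz <- if (!is.null(pump)) 5 / pump$transit_duration_s else 2.5
  }
  check_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (cutoff_hz >= nyquist) {
    stop_invalid(sprintf("`cutoff_hz` (%g) must be below the Nyquist frequency (%g Hz).",
                         cutoff_hz, nyquist))
  }
  if (nrow(attr(trace, "gaps") %||% tibble()) > 0) {
    trace <- resample_uniform(trace)
  }
  x <- trace$frequency_hz
  mu <- mean(x)
  xc <- x - mu
  pad <- min(length(xc) - 1L, max(50L, ceiling(3 / (cutoff_hz * dt))))
  xp <- c(rev(xc[seq_len(pad) + 1L]), xc, rev(xc[length(xc) - seq_len(pad)]))
  bf <- signal::butter(4, cutoff_hz / nyquist, type = "low")
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(pad + 1L):(pad + length(xc))] + mu
  out <- frequency_trace(trace$time_s, y, sample_interval_s = dt,
                         metadata = attr(trace, "metadata") %||% list())
  attr(out, "lowpass_cutoff_hz") <- cutoff_hz
  out
}

#' Estimate the slowly varying baseline of a trace
#'
#' Rolling robust (median) baseline with transit-peak masking: a first-pass
#' rolling median flags samples deviating by more than 4 robust SDs, those
#' samples are replaced by the first-pass value, and the rolling median is
#' recomputed. The median runs on a decimated grid (the baseline varies on
#' drift timescales) and is interpolated back to every sample.
#'
#' @param trace A `frequency_trace` tibble (typically already filtered).
#' @param window_s Rolling window in seconds; should span several pump
#'   reversals so transit peaks cannot deflect the median. Default 30.
#' @return The input tibble with an added `baseline_hz` column.
#' @export
estimate_baseline <- function(trace, window_s = 30) {
  check_number(window_s, "window_s", positive = TRUE)
  dt <- trace_interval(trace)
  x <- trace$frequency_hz
  n <- length(x)
  dec <- max(1L, ceiling(window_s / dt / 1501))
  idx <- seq(1L, n, by = dec)
  xd <- x[idx]
  k <- odd_window(min(length(xd), window_s / (dt * dec)))
  if (k > length(xd)) k <- length(xd) - (1L - length(xd) %% 2L)
  if (length(xd) < 3L) {
    base_d <- rep(median(xd), length(xd))
  } else {
    base_d <- as.numeric(runmed(xd, k, endrule = "median"))
    resid <- xd - base_d
    s <- robust_sd(resid)
    if (s > 0) {
      masked <- xd
      masked[abs(resid) > 4 * s] <- base_d[abs(resid) > 4 * s]
      base_d <- as.numeric(runmed(masked, k, endrule = "median"))
    }
  }
  baseline <- if (length(idx) == n) base_d else {
    approx(trace$time_s[idx], base_d, xout = trace$time_s, rule = 2)$y
  }
  out <- trace
  out$baseline_hz <- baseline
  out
}

#' Detect transit peak pairs in a filtered trace
#'
#' Each passage of the pellet through the sensor produces two frequency
#' extrema (one per tine tip). Samples whose baseline-subtracted magnitude
#' exceeds `min_prominence` are grouped into candidate extrema; consecutive
#' extrema closer than the transit duration are paired into one transit and
#' their signed heights averaged. Unpaired extrema are kept but flagged
#' `singleton-peak`; pairs whose heights differ by more than 25% of the
#' larger are flagged `asymmetric-pair` but retained.
#'
#' @param trace A `frequency_trace` with a `baseline_hz` column (from
#'   [estimate_baseline()]); if absent, the baseline is estimated with
#'   defaults.
#' @param pump A [pump_schedule()]; supplies the pairing window.
#' @param min_prominence_hz Minimum extremum magnitude. Default: 5 times the
#'   robust SD of the baseline-subtracted trace, with a 1e-4 Hz floor.
#' @return A tibble of class `peak_pairs`: columns `transit_index`,
#'   `time_s`, `t1_s`, `t2_s`, `h1_hz`, `h2_hz`, `baseline_hz`,
#'   `mean_height_hz`, `asymmetry`, `flags`.
#' @export
detect_transits <- function(trace, pump, min_prominence_hz = NULL) {
  stopifnot(inherits(pump, "pump_schedule"))
  empty <- tibble(
    transit_index = integer(), time_s = numeric(), t1_s = numeric(),
    t2_s = numeric(), h1_hz = numeric(), h2_hz = numeric(),
    baseline_hz = numeric(), mean_height_hz = numeric(),
    asymmetry = numeric(), flags = character()
  )
  if (nrow(trace) == 0) return(structure(empty, class = c("peak_pairs", class(empty))))
  if (!"baseline_hz" %in% names(trace)) trace <- estimate_baseline(trace)
  resid <- trace$frequency_hz - trace$baseline_hz
  if (is.null(min_prominence_hz)) {
    min_prominence_hz <- max(5 * robust_sd(resid), 1e-4)
  }
  check_number(min_prominence_hz, "min_prominence_hz", positive = TRUE)

  above <- which(abs(resid) > min_prominence_hz)
  if (length(above) == 0) {
    return(structure(empty, class = c("peak_pairs", class(empty))))
  }
  dt <- trace_interval(trace)
  # Cluster above-threshold samples into transits: the two lobes of one
  # transit sit ~transit_duration/2 apart, while consecutive transits are a
  # full reversal period apart, so a 0.75x-transit-duration gap separates
  # transits without splitting one.
  gap <- max(1L, floor(0.75 * pump$transit_duration_s / dt))
  breaks <- which(diff(above) > gap)
  cl_start <- above[c(1L, breaks + 1L)]
  cl_end <- above[c(breaks, length(above))]

  # Within each cluster, take the largest-magnitude sample as the first
  # extremum, mask a quarter transit duration around it (one lobe), and take
  # the largest remaining above-threshold sample as the partner extremum.
  mask_w <- 0.25 * pump$transit_duration_s
  pairs <- purrr::map_dfr(seq_along(cl_start), function(ci) {
    seg <- cl_start[ci]:cl_end[ci]
    seg <- seg[abs(resid[seg]) > min_prominence_hz]
    j1 <- seg[which.max(abs(resid[seg]))]
    # The partner lobe must be comparable to the primary; filter skirts and
    # stray samples just above threshold do not make a pair.
    rest <- seg[abs(trace$time_s[seg] - trace$time_s[j1]) > mask_w]
    rest <- rest[abs(resid[rest]) > 0.1 * abs(resid[j1])]
    if (length(rest) == 0) {
      return(tibble(
        time_s = trace$time_s[j1], t1_s = trace$time_s[j1], t2_s = NA_real_,
        h1_hz = resid[j1], h2_hz = NA_real_,
        baseline_hz = trace$baseline_hz[j1],
        mean_height_hz = resid[j1],
        asymmetry = NA_real_, flags = "singleton-peak"
      ))
    }
    j2 <- rest[which.max(abs(resid[rest]))]
    jj <- sort(c(j1, j2))
    h1 <- resid[jj[1]]; h2 <- resid[jj[2]]
    asym <- abs(h1 - h2) / max(abs(h1), abs(h2))
    tibble(
      time_s = mean(trace$time_s[jj]),
      t1_s = trace$time_s[jj[1]], t2_s = trace$time_s[jj[2]],
      h1_hz = h1, h2_hz = h2,
      baseline_hz = mean(trace$baseline_hz[jj]),
      mean_height_hz = (h1 + h2) / 2,
      asymmetry = asym,
      flags = if (asym > 0.25) "asymmetric-pair" else ""
    )
  })
  out <- pairs
  out <- dplyr::mutate(out, transit_index = dplyr::row_number(), .before = 1)
  structure(out, class = c("peak_pairs", class(empty)),
            min_prominence_hz = min_prominence_hz)
}

#' Convert peak pairs to a calibrated buoyant-mass series
#'
#' Multiplies each transit's mean peak height by the point-mass calibration
#' constant (downward peaks map to positive mass). Singleton-flagged
#' extrema are excluded by default; each point carries the calibration's
#' mass resolution as its uncertainty.
#'
#' @param pairs A `peak_pairs` tibble from [detect_transits()].
#' @param cal A [point_mass_calibration()].
#' @param include_singletons Keep singleton-flagged extrema? Default FALSE.
#' @param fluid_label Optional fluid label stored on the series.
#' @return A tibble of class `mass_series`: columns `time_min`, `mass_ug`,
#'   `uncertainty_ug`.
#' @export
to_mass_series <- function(pairs, cal, include_singletons = FALSE,
                           fluid_label = "") {
  stopifnot(inherits(cal, "point_mass_calibration"))
  keep <- if (include_singletons) rep(TRUE, nrow(pairs)) else
    !grepl("singleton-peak", pairs$flags)
  pr <- pairs[keep, , drop = FALSE]
  unc <- if (is.na(cal$resolution_g)) NA_real_ else cal$resolution_g * MICROGRAMS_PER_GRAM
  out <- tibble(
    time_min = pr$time_s / 60,
    mass_ug = shift_to_mass(pr$mean_height_hz, cal),
    uncertainty_ug = unc
  )
  out <- new_tibble(out, nrow = nrow(out), class = "mass_series")
  attr(out, "fluid") <- fluid_label
  # Smallest mass the detection threshold can witness: transits below the
  # prominence floor never enter the series.
  prom <- attr(pairs, "min_prominence_hz")
  if (!is.null(prom)) {
    attr(out, "detection_floor_ug") <- abs(shift_to_mass(-prom, cal))
  }
  out
}
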