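# Sensor calibration: bulk fluid density, point mass, and mass resolution.

#' Fit the bulk-density calibration
#'
#' Ordinary least-squares line of mean resonance frequency against known
#' fluid density; the slope (Hz per g/mL) converts frequency readings to
#' fluid densities. Accepts either a summary data frame or two vectors.
#'
#' @param data Data frame with columns `density_g_ml` and either
#'   `mean_frequency_hz` or per-sample `frequency_hz` (in which case means
#'   are taken per density), e.g. the output of [make_density_fixture()].
#'   May be omitted if `mean_frequencies_hz`/`known_densities_g_ml` are given.
#' @param mean_frequencies_hz,known_densities_g_ml Equal-length vectors of
#'   per-fluid mean frequency and known density (used when `data` is NULL).
#' @return A [density_calibration()] with `r_squared` and `residual_sd_hz`
#'   filled in; the reference point is the densest-to-lightest midpoint on
#'   the fitted line and `valid_range` spans the fitted densities.
#' @examples
#' fit_density_calibration(
#'   mean_frequencies_hz = c(474.25, 474.25 - 0.02 * 300),
#'   known_densities_g_ml = c(1.00, 1.02)
#' )
#' @export
fit_density_calibration <- function(data = NULL, mean_frequencies_hz = NULL,
                                    known_densities_g_ml = NULL) {
  if (!is.null(data)) {
    data <- as_tibble(data)
    if (!"density_g_ml" %in% names(data)) {
      stop_invalid("`data` must contain a `density_g_ml` column.")
    }
    if ("mean_frequency_hz" %in% names(data)) {
      known_densities_g_ml <- data$density_g_ml
      mean_frequencies_hz <- data$mean_frequency_hz
    } else if ("frequency_hz" %in% names(data)) {
      sm <- dplyr::summarise(
        dplyr::group_by(data, .data$density_g_ml),
        mean_frequency_hz = mean(.data$frequency_hz), .groups = "drop"
      )
      known_densities_g_ml <- sm$density_g_ml
      mean_frequencies_hz <- sm$mean_frequency_hz
    } else {
      stop_invalid("`data` must contain `mean_frequency_hz` or `frequency_hz`.")
    }
  }
  if (length(mean_frequencies_hz) != length(known_densities_g_ml)) {
    stop_invalid("Frequency and density vectors must have equal length.")
  }
  if (length(unique(known_densities_g_ml)) < 2) {
    stop_insufficient("Need at least two distinct densities to fit a line.")
  }
  fit <- lm(mean_frequencies_hz ~ known_densities_g_ml)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop_inconsistent("Fitted density slope is non-negative; denser fluid should lower the frequency.")
  }
  ref_density <- mean(range(known_densities_g_ml))
  ref_frequency <- unname(coef(fit)[1]) + slope * ref_density
  resid <- stats::residuals(fit)
  ss_tot <- sum((mean_frequencies_hz - mean(mean_frequencies_hz))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  rsd <- if (length(resid) > 2) sqrt(sum(resid^2) / (length(resid) - 2)) else 0
  density_calibration(
    slope_hz_per_g_ml = slope,
    reference_frequency_hz = ref_frequency,
    reference_density_g_ml = ref_density,
    valid_range = range(known_densities_g_ml),
    r_squared = r2,
    residual_sd_hz = rsd
  )
}

#' Fit the point-mass calibration from replicate bead transits
#'
#' A microbead of known mass and density is passed through the sensor
#' several times in a fluid of known density. Its buoyant mass (from
#' [buoyant_mass()]) divided by the mean measured peak height gives the
#' point-mass calibration constant K (g per Hz). K uses magnitudes, so it is
#' invariant to the peak-height sign convention.
#'
#' @param replicate_heights_hz Signed mean peak heights of the replicate
#'   bead transits (Hz); >= 2 values.
#' @param bead A [pellet_state()] describing the bead.
#' @param fl The [fluid()] the bead was measured in.
#' @return A [point_mass_calibration()] (resolution NA until
#'   [estimate_resolution()] is run).
#' @examples
#' fit_point_mass_calibration(rep(-0.05, 5), pellet_state(540, 1.2), fluid(1.0))
#' @export
fit_point_mass_calibration <- function(replicate_heights_hz, bead, fl) {
  if (length(replicate_heights_hz) < 2) {
    stop_insufficient("Need at least two replicate bead transits.")
  }
  mb <- buoyant_mass(bead, fl)
  if (mb == 0) {
    stop_degenerate("Bead buoyant mass is zero in this fluid; it cannot calibrate the sensor.")
  }
  mean_h <- mean(replicate_heights_hz)
  if (mean_h == 0) {
    stop_degenerate("Mean replicate peak height is zero; calibration is degenerate.")
  }
  point_mass_calibration(
    constant_g_per_hz = abs(mb / MICROGRAMS_PER_GRAM) / abs(mean_h),
    bead_buoyant_mass_ug = mb,
    n_replicates = length(replicate_heights_hz)
  )
}

#' Estimate the sensor's point-mass resolution
#'
#' The width of the distribution of replicate frequency-change measurements
#' of a constant reference bead, interpreted as the sample standard
#' deviation and converted to mass through the calibration constant:
#' `resolution = multiplier * K * sd(heights)`.
#'
#' @param replicate_heights_hz Replicate peak heights (Hz); >= 3 values.
#' @param cal A [point_mass_calibration()].
#' @param multiplier Width multiplier on the 1-sigma SD; default 1.
#' @return The input calibration with `resolution_g` filled in.
#' @export
estimate_resolution <- function(replicate_heights_hz, cal, multiplier = 1) {
  stopifnot(inherits(cal, "point_mass_calibration"))
  if (length(replicate_heights_hz) < 3) {
    stop_insufficient("Need at least three replicates to estimate the resolution.")
  }
  check_number(multiplier, "multiplier", positive = TRUE)
  cal$resolution_g <- multiplier * cal$constant_g_per_hz * sd(replicate_heights_hz)
  cal$n_replicates <- length(replicate_heights_hz)
  cal
}
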