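# Buoyant-mass physics and linear sensor calibration models.
#
# Internal unit conventions: mass in micrograms (ug), volume in nanolitres
# (nL), density in g/mL, frequency in Hz. One ug divided by one g/mL is one
# nL, so no hidden conversion factors appear in the physics. Conversions to
# grams happen only where the point-mass calibration constant (g per Hz)
# meets peak heights.

#' Describe a pellet by its absolute mass and density
#'
#' A pellet is characterised by its absolute (in vacuo) mass \eqn{m} and its
#' density \eqn{\rho_{pellet}}; its volume follows as \eqn{m/\rho_{pellet}}.
#'
#' @param absolute_mass_ug Absolute (in vacuo) mass in micrograms; >= 0.
#' @param density_g_ml Pellet density in g/mL; > 0.
#' @return An object of class `pellet_state`: a list with fields
#'   `absolute_mass_ug`, `density_g_ml` and the derived `volume_nl`.
#' @examples
#' pellet_state(300, 1.2)
#' @export
pellet_state <- function(absolute_mass_ug, density_g_ml) {
  check_number(absolute_mass_ug, "absolute_mass_ug", nonneg = TRUE)
  check_number(density_g_ml, "density_g_ml", positive = TRUE)
  structure(
    list(
      absolute_mass_ug = absolute_mass_ug,
      density_g_ml = density_g_ml,
      volume_nl = absolute_mass_ug / density_g_ml
    ),
    class = "pellet_state"
  )
}

#' Describe the fluid filling the sensor
#'
#' @param density_g_ml Fluid density in g/mL; > 0.
#' @param label Free-text label, e.g. `"simulated intestinal fluid pH 7.0"`.
#' @return An object of class `fluid`.
#' @examples
#' fluid(1.003, "simulated intestinal fluid pH 7.0")
#' @export
fluid <- function(density_g_ml, label = "") {
  check_number(density_g_ml, "density_g_ml", positive = TRUE)
  structure(
    list(density_g_ml = density_g_ml, label = as.character(label)[1]),
    class = "fluid"
  )
}

#' Buoyant mass of a pellet in a fluid
#'
#' The sensor weighs a pellet immersed in fluid, so it reports the buoyant
#' mass \deqn{m_b = m\,(1 - \rho_{fluid}/\rho_{pellet}) =
#' V\,(\rho_{pellet} - \rho_{fluid}),} positive when the pellet is denser
#' than the fluid (the pellet adds net mass to the vibrating tube, so the
#' resonance frequency dips), negative when the pellet is lighter, and zero
#' when the densities match.
#'
#' @param pellet A [pellet_state()].
#' @param fl A [fluid()].
#' @return Signed buoyant mass in micrograms.
#' @examples
#' buoyant_mass(pellet_state(300, 1.2), fluid(1.0)) # 50 ug
#' @export
buoyant_mass <- function(pellet, fl) {
  stopifnot(inherits(pellet, "pellet_state"), inherits(fl, "fluid"))
  pellet$absolute_mass_ug * (1 - fl$density_g_ml / pellet$density_g_ml)
}

#' Linear bulk-density calibration of the sensor
#'
#' A fluid-filled vibrating tube resonates lower when filled with a denser
#' fluid; over a narrow density span the relationship is linear. The model is
#' anchored at a reference point: `f = reference_frequency_hz +
#' slope_hz_per_g_ml * (rho - reference_density_g_ml)`.
#'
#' @param slope_hz_per_g_ml Frequency change per unit fluid density; must be
#'   negative (denser fluid lowers the resonance frequency).
#' @param reference_frequency_hz Resonance frequency at the reference density.
#' @param reference_density_g_ml Reference fluid density in g/mL.
#' @param valid_range Length-2 numeric, the density span (g/mL) covered by
#'   the calibration fixture.
#' @param r_squared,residual_sd_hz Optional fit diagnostics.
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(slope_hz_per_g_ml, reference_frequency_hz,
                                reference_density_g_ml,
                                valid_range = c(1.00, 1.08),
                                r_squared = NA_real_,
                                residual_sd_hz = NA_real_) {
  check_number(slope_hz_per_g_ml, "slope_hz_per_g_ml")
  if (slope_hz_per_g_ml >= 0) {
    stop_invalid("`slope_hz_per_g_ml` must be negative: denser fluid lowers the resonance frequency.")
  }
  check_number(reference_frequency_hz, "reference_frequency_hz", positive = TRUE)
  check_number(reference_density_g_ml, "reference_density_g_ml", positive = TRUE)
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    stop_invalid("`valid_range` must be c(min, max) with min < max.")
  }
  structure(
    list(
      slope_hz_per_g_ml = slope_hz_per_g_ml,
      reference_frequency_hz = reference_frequency_hz,
      reference_density_g_ml = reference_density_g_ml,
      valid_range = as.numeric(valid_range),
      r_squared = r_squared,
      residual_sd_hz = residual_sd_hz
    ),
    class = "density_calibration"
  )
}

#' Point-mass calibration of the sensor
#'
#' Converts transit peak heights (Hz) to buoyant masses. The constant K has
#' units of grams per Hz; `resolution_g` is the smallest resolvable buoyant
#' mass, estimated from the spread of replicate measurements of a reference
#' bead (see [estimate_resolution()]).
#'
#' @param constant_g_per_hz Calibration constant K in g/Hz; > 0.
#' @param resolution_g Mass resolution in grams (NA until estimated).
#' @param bead_buoyant_mass_ug Buoyant mass of the calibration bead, ug.
#' @param n_replicates Number of replicate bead transits used.
#' @return An object of class `point_mass_calibration`.
#' @examples
#' point_mass_calibration(1.8e-3, resolution_g = 700e-9)
#' @export
point_mass_calibration <- function(constant_g_per_hz, resolution_g = NA_real_,
                                   bead_buoyant_mass_ug = NA_real_,
                                   n_replicates = NA_integer_) {
  check_number(constant_g_per_hz, "constant_g_per_hz", positive = TRUE)
  if (!is.na(resolution_g)) check_number(resolution_g, "resolution_g", nonneg = TRUE)
  structure(
    list(
      constant_g_per_hz = constant_g_per_hz,
      resolution_g = resolution_g,
      bead_buoyant_mass_ug = bead_buoyant_mass_ug,
      n_replicates = n_replicates
    ),
    class = "point_mass_calibration"
  )
}

#' Convert a peak height to a buoyant mass
#'
#' A pellet denser than the fluid momentarily adds mass to the tube, so its
#' transit peaks point *down* (negative height relative to baseline) and map
#' to *positive* buoyant mass: `mass_ug = -height_hz * K * 1e6`.
#' Exact inverse of [mass_to_shift()].
#'
#' @param height_hz Signed peak height in Hz (negative = downward peak).
#' @param cal A [point_mass_calibration()].
#' @return Signed buoyant mass in micrograms. Vectorised over `height_hz`.
#' @examples
#' shift_to_mass(-0.1, point_mass_calibration(1.8e-3)) # 180 ug
#' @export
shift_to_mass <- function(height_hz, cal) {
  stopifnot(inherits(cal, "point_mass_calibration"))
  -height_hz * cal$constant_g_per_hz * MICROGRAMS_PER_GRAM
}

#' Convert a buoyant mass to the peak height it produces
#'
#' @param mass_ug Signed buoyant mass in micrograms.
#' @param cal A [point_mass_calibration()].
#' @return Signed peak height in Hz (negative for sinking pellets).
#' @export
mass_to_shift <- function(mass_ug, cal) {
  stopifnot(inherits(cal, "point_mass_calibration"))
  -mass_ug / (cal$constant_g_per_hz * MICROGRAMS_PER_GRAM)
}

#' Convert a resonance frequency to a fluid density
#'
#' Inverts the linear bulk-density model:
#' `rho = reference_density + (f - reference_frequency)/slope`.
#' Warns when `f` lies outside the frequency image of the calibration's
#' valid density range.
#'
#' @param frequency_hz Resonance frequency (Hz); vectorised.
#' @param cal A [density_calibration()].
#' @return Fluid density in g/mL.
#' @export
density_from_frequency <- function(frequency_hz, cal) {
  stopifnot(inherits(cal, "density_calibration"))
  if (cal$slope_hz_per_g_ml == 0) stop_invalid("Calibration slope must be nonzero.")
  f_range <- sort(frequency_from_density(cal$valid_range, cal))
  eps <- 1e-9 * max(1, abs(f_range))
  if (any(frequency_hz < f_range[1] - eps[1] |
            frequency_hz > f_range[2] + eps[2], na.rm = TRUE)) {
    warn("Frequency outside the calibrated density range; extrapolating the linear model.")
  }
  cal$reference_density_g_ml +
    (frequency_hz - cal$reference_frequency_hz) / cal$slope_hz_per_g_ml
}

#' Predicted resonance frequency at a fluid density
#'
#' @param density_g_ml Fluid density (g/mL); vectorised.
#' @param cal A [density_calibration()].
#' @return Resonance frequency in Hz.
#' @export
frequency_from_density <- function(density_g_ml, cal) {
  stopifnot(inherits(cal, "density_calibration"))
  cal$reference_frequency_hz +
    cal$slope_hz_per_g_ml * (density_g_ml - cal$reference_density_g_ml)
}

#' Recover pellet mass, volume and density from two-fluid measurements
#'
#' Buoyant mass confounds changes in pellet mass with changes in pellet
#' density. Measuring the same pellet in two fluids of different densities
#' separates them: from \eqn{m_{b,i} = V(\rho_p - \rho_{f,i})},
#' \deqn{V = (m_{b,1} - m_{b,2})/(\rho_{f,2} - \rho_{f,1}), \quad
#'       m = m_{b,1} + V \rho_{f,1}, \quad \rho_p = m/V.}
#'
#' @param mb1_ug Buoyant mass (ug) measured in `fluid1`.
#' @param fluid1,fluid2 [fluid()] objects with distinct densities.
#' @param mb2_ug Buoyant mass (ug) measured in `fluid2`.
#' @return A `two_fluid_solution`: list with `absolute_mass_ug`, `volume_nl`,
#'   `density_g_ml`.
#' @examples
#' solve_two_fluid(50, fluid(1.0), 25, fluid(1.1))
#' @export
solve_two_fluid <- function(mb1_ug, fluid1, mb2_ug, fluid2) {
  stopifnot(inherits(fluid1, "fluid"), inherits(fluid2, "fluid"))
  check_number(mb1_ug, "mb1_ug")
  check_number(mb2_ug, "mb2_ug")
  d1 <- fluid1$density_g_ml
  d2 <- fluid2$density_g_ml
  if (d1 == d2) {
    stop_degenerate("The two fluids must have different densities.")
  }
  volume_nl <- (mb1_ug - mb2_ug) / (d2 - d1)
  if (volume_nl <= 0) {
    stop_inconsistent(sprintf(
      "Inconsistent measurements: implied pellet volume %g nL is not positive.",
      volume_nl
    ))
  }
  mass_ug <- mb1_ug + volume_nl * d1
  structure(
    list(
      absolute_mass_ug = mass_ug,
      volume_nl = volume_nl,
      density_g_ml = mass_ug / volume_nl
    ),
    class = "two_fluid_solution"
  )
}

#' @export
print.pellet_state <- function(x, ...) {
  cat(sprintf(
    "<pellet_state> m = %g ug, rho = %g g/mL, V = %g nL\n",
    x$absolute_mass_ug, x$density_g_ml, x$volume_nl
  ))
  invisible(x)
}

#' @export
print.two_fluid_solution <- function(x, ...) {
  cat(sprintf(
    "<two_fluid_solution> m = %g ug, V = %g nL, rho = %g g/mL\n",
    x$absolute_mass_ug, x$volume_nl, x$density_g_ml
  ))
  invisible(x)
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf(
    "<density_calibration> slope = %g Hz/(g/mL), ref = (%g Hz, %g g/mL), range [%g, %g] g/mL\n",
    x$slope_hz_per_g_ml, x$reference_frequency_hz, x$reference_density_g_ml,
    x$valid_range[1], x$valid_range[2]
  ))
  invisible(x)
}

#' @export
print.point_mass_calibration <- function(x, ...) {
  cat(sprintf(
    "<point_mass_calibration> K = %g g/Hz, resolution = %s ng, n = %s\n",
    x$constant_g_per_hz,
    ifelse(is.na(x$resolution_g), "NA", format(x$resolution_g * 1e9)),
    format(x$n_replicates)
  ))
  invisible(x)
}
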