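# broom-style tidiers for fitted objects.

#' Tidy a fitted dissolution profile
#'
#' `tidy()` returns the fitted constant-rate segments (one row per
#' segment); `glance()` returns the one-row summary metrics with model
#' size.
#'
#' @param x A `dissolution_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dissolution_profile <- function(x, ...) {
  as_tibble(x$segments)
}

#' @rdname tidy.dissolution_profile
#' @export
glance.dissolution_profile <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble(
      n_points = nrow(x$series),
      n_segments = nrow(x$segments),
      n_jumps = nrow(x$jumps)
    )
  )
}

#' Tidy calibration records
#'
#' One row per calibration parameter, broom style.
#'
#' @param x A `density_calibration` or `point_mass_calibration`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.density_calibration <- function(x, ...) {
  tibble(
    term = c("slope_hz_per_g_ml", "reference_frequency_hz",
             "reference_density_g_ml"),
    estimate = c(x$slope_hz_per_g_ml, x$reference_frequency_hz,
                 x$reference_density_g_ml)
  )
}

#' @rdname tidy.density_calibration
#' @export
glance.density_calibration <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    residual_sd_hz = x$residual_sd_hz,
    valid_min_g_ml = x$valid_range[1],
    valid_max_g_ml = x$valid_range[2]
  )
}

#' @rdname tidy.density_calibration
#' @export
tidy.point_mass_calibration <- function(x, ...) {
  tibble(
    term = c("constant_g_per_hz", "resolution_g", "bead_buoyant_mass_ug"),
    estimate = c(x$constant_g_per_hz, x$resolution_g, x$bead_buoyant_mass_ug)
  )
}
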