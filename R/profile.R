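# From calibrated buoyant-mass series to a dissolution profile:
# piecewise-linear phases, abrupt jump events, and summary metrics.

# Closed-form per-segment least-squares machinery on prefix sums, so binary
# segmentation can evaluate any candidate split in O(1).
make_segment_fitter <- function(t, y) {
  t0 <- mean(t); y0 <- mean(y)
  x <- t - t0; z <- y - y0
  cs <- function(v) c(0, cumsum(v))
  Sx <- cs(x); Sz <- cs(z); Sxx <- cs(x^2); Sxz <- cs(x * z); Szz <- cs(z^2)
  function(i, j) {
    n <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]; sz <- Sz[j + 1] - Sz[i]
    sxx <- Sxx[j + 1] - Sxx[i]; sxz <- Sxz[j + 1] - Sxz[i]
    szz <- Szz[j + 1] - Szz[i]
    cxx <- sxx - sx^2 / n
    cxz <- sxz - sx * sz / n
    czz <- szz - sz^2 / n
    slope <- if (cxx > 1e-12 * max(1, sxx)) cxz / cxx else 0
    rss <- max(0, czz - slope * cxz)
    mean_t <- sx / n + t0
    mean_y <- sz / n + y0
    list(
      n = n, rate = slope, intercept = mean_y - slope * mean_t,
      rss = rss, sxx_c = cxx, mean_t = mean_t, mean_y = mean_y
    )
  }
}

# Greedy binary segmentation minimising per-segment linear RSS with a
# per-changepoint penalty. Returns sorted split indices (last index of each
# segment except the final one).
binseg_linear <- function(t, y, penalty, min_seg = 3L, max_segments = 6L) {
  n <- length(y)
  fit <- make_segment_fitter(t, y)
  best_split <- function(i, j) {
    ks <- seq.int(i + min_seg - 1L, j - min_seg)
    if (length(ks) == 0 || ks[1] > ks[length(ks)]) return(NULL)
    whole <- fit(i, j)$rss
    gains <- vapply(ks, function(k) whole - fit(i, k)$rss - fit(k + 1L, j)$rss,
                    numeric(1))
    kbest <- ks[which.max(gains)]
    list(k = kbest, gain = max(gains))
  }
  splits <- integer()
  segs <- list(c(1L, n))
  cand <- list(best_split(1L, n))
  while (length(splits) + 1L < max_segments) {
    gains <- vapply(cand, function(cc) if (is.null(cc)) -Inf else cc$gain,
                    numeric(1))
    b <- which.max(gains)
    if (!is.finite(gains[b]) || gains[b] <= penalty) break
    k <- cand[[b]]$k
    ij <- segs[[b]]
    splits <- sort(c(splits, k))
    segs[[b]] <- c(ij[1], k)
    segs[[length(segs) + 1L]] <- c(k + 1L, ij[2])
    cand[[b]] <- best_split(ij[1], k)
    cand[[length(cand) + 1L]] <- best_split(k + 1L, ij[2])
  }
  splits
}

#' Detect abrupt mass-loss events in a buoyant-mass series
#'
#' Scans consecutive measurement pairs for drops of at least `min_drop_ug`
#' completed within `max_span_s`; adjacent qualifying intervals are merged
#' into one event. Events are reported with their raw mass change; when a
#' profile is fitted, jump magnitudes are refined against the flanking
#' segment fits (see [fit_dissolution_profile()]).
#'
#' @param series A `mass_series` tibble (`time_min`, `mass_ug`, ...).
#' @param min_drop_ug Minimum drop (ug) to count as a jump; should exceed
#'   both the measurement uncertainty and the largest per-interval drop the
#'   smooth phases can produce.
#' @param max_span_s Maximum duration of the event (seconds).
#' @return A tibble of class `jump_table`: `time_min`, `dmass_ug` (signed,
#'   negative = loss), `span_s`, plus the event's row range.
#' @export
detect_jumps <- function(series, min_drop_ug, max_span_s = 30) {
  check_number(min_drop_ug, "min_drop_ug", positive = TRUE)
  check_number(max_span_s, "max_span_s", positive = TRUE)
  empty <- tibble(
    time_min = numeric(), dmass_ug = numeric(), span_s = numeric(),
    row_start = integer(), row_end = integer()
  )
  n <- nrow(series)
  if (n < 2) return(structure(empty, class = c("jump_table", class(empty))))
  unc <- suppressWarnings(stats::median(series$uncertainty_ug, na.rm = TRUE))
  if (is.finite(unc) && min_drop_ug <= unc) {
    warn("`min_drop_ug` does not exceed the per-point uncertainty; spurious jumps are likely.")
  }
  dm <- diff(series$mass_ug)
  dt_s <- diff(series$time_min) * 60
  qual <- dm <= -min_drop_ug & dt_s <= max_span_s
  if (!any(qual)) return(structure(empty, class = c("jump_table", class(empty))))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- tibble(i0 = starts[r$values], i1 = ends[r$values])
  out <- purrr::pmap_dfr(ev, function(i0, i1) {
    tibble(
      time_min = (series$time_min[i0] + series$time_min[i1 + 1]) / 2,
      dmass_ug = series$mass_ug[i1 + 1] - series$mass_ug[i0],
      span_s = (series$time_min[i1 + 1] - series$time_min[i0]) * 60,
      row_start = i0, row_end = i1 + 1L
    )
  })
  structure(out, class = c("jump_table", class(empty)))
}

#' Segment a buoyant-mass series into constant-rate phases
#'
#' Places changepoints by binary segmentation over per-segment linear
#' least-squares cost: a split is accepted while the reduction in total
#' squared residual exceeds a per-changepoint penalty (BIC-style,
#' `3 * sigma^2 * log(n)` by default, with sigma estimated robustly from
#' first differences). Each segment reports its fitted dissolution rate.
#'
#' @param series A `mass_series` tibble with at least 3 points.
#' @param max_segments Upper bound on the number of segments.
#' @param penalty Per-changepoint penalty (ug^2); NULL for the default.
#' @param min_seg Minimum points per segment (default 3).
#' @return A tibble of class `segment_table`: `t_start_min`, `t_end_min`,
#'   `rate_ug_min`, `intercept_ug`, `n_points`, `rss`, `rate_se`. Segment
#'   boundaries abut at midpoints between neighbouring data points, so
#'   segments are contiguous and non-overlapping.
#' @export
segment_profile <- function(series, max_segments = 6, penalty = NULL,
                            min_seg = 3) {
  n <- nrow(series)
  if (n < 3) stop_insufficient("Need at least 3 points to segment a series.")
  max_segments <- as.integer(max_segments)
  if (max_segments < 1) stop_invalid("`max_segments` must be >= 1.")
  if (n < 2 * (max_segments + 1)) {
    max_segments <- max(1L, n %/% (2L * min_seg))
    warn(sprintf("Too few points for the requested segments; reduced to %d.", max_segments))
  }
  t <- series$time_min
  y <- series$mass_ug
  if (is.null(penalty)) {
    sigma <- robust_sd(diff(y)) / sqrt(2)
    penalty <- 3 * max(sigma, 1e-3)^2 * log(n)
  }
  check_number(penalty, "penalty", nonneg = TRUE)
  splits <- if (max_segments == 1L) integer() else
    binseg_linear(t, y, penalty, min_seg = as.integer(min_seg),
                  max_segments = max_segments)
  fit <- make_segment_fitter(t, y)
  bounds <- c(0L, splits, n)
  segs <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(s) {
    i <- bounds[s] + 1L; j <- bounds[s + 1L]
    ft <- fit(i, j)
    t_start <- if (i == 1L) t[1] else (t[i - 1] + t[i]) / 2
    t_end <- if (j == n) t[n] else (t[j] + t[j + 1]) / 2
    rate_se <- if (ft$n > 2 && ft$sxx_c > 0) {
      sqrt(ft$rss / (ft$n - 2) / ft$sxx_c)
    } else NA_real_
    tibble(
      t_start_min = t_start, t_end_min = t_end,
      rate_ug_min = ft$rate, intercept_ug = ft$intercept,
      n_points = ft$n, rss = ft$rss, rate_se = rate_se
    )
  })
  structure(segs, class = c("segment_table", class(segs)))
}

# Refine a jump's magnitude against the fitted lines of its flanking
# segments. The scheduled event is modelled as a linear ramp between
# (t0, before(t0)) and (t1, after(t1)) with the after-phase rate running
# concurrently; Delta = before(t0) - after(t1) - |r_after|-corrected trend.
# (t0, t1) are chosen by least squares over the points inside the event.
refine_jump <- function(jump, series, seg_before, seg_after) {
  line_val <- function(seg, t) seg$intercept_ug + seg$rate_ug_min * t
  tb <- series$time_min[jump$row_start]
  ta <- series$time_min[jump$row_end]
  interior <- series[series$time_min > tb & series$time_min < ta, , drop = FALSE]
  r_a <- seg_after$rate_ug_min
  delta_at <- function(t0, t1) {
    line_val(seg_before, t0) - line_val(seg_after, t1) + r_a * (t1 - t0)
  }
  if (nrow(interior) == 0) {
    # No samples inside the event: place the ramp across the whole gap.
    return(delta_at(tb, ta))
  }
  grid0 <- seq(tb, max(interior$time_min), length.out = 16)
  grid1 <- seq(min(interior$time_min), ta, length.out = 16)
  best <- c(rss = Inf, t0 = tb, t1 = ta)
  for (t0 in grid0) {
    v0 <- line_val(seg_before, t0)
    for (t1 in grid1) {
      if (t1 <= t0) next
      v1 <- line_val(seg_after, t1)
      pred <- v0 + (v1 - v0) * pmin(1, pmax(0, (interior$time_min - t0) / (t1 - t0)))
      rss <- sum((interior$mass_ug - pred)^2)
      if (rss < best["rss"]) best <- c(rss = rss, t0 = t0, t1 = t1)
    }
  }
  delta_at(best[["t0"]], best[["t1"]])
}

#' Summary metrics of a dissolution profile
#'
#' Computes the headline numbers of a single-pellet dissolution run:
#' starting mass (robust mean of the first segment), residual "ghost" mass
#' (robust mean of the final segment, or 0 when the series ends below the
#' dissolved threshold), the ghost fraction in percent, onset time (first
#' segment or jump whose rate magnitude exceeds `rate_floor_ug_min`), and
#' completion time (first measurement below the dissolved threshold).
#'
#' @param series A `mass_series` tibble.
#' @param segments A `segment_table` from [segment_profile()].
#' @param jumps A `jump_table` from [detect_jumps()] (may be empty).
#' @param dissolved_threshold_ug Mass below which the pellet counts as
#'   dissolved; a common choice is 3x the calibration resolution.
#' @param rate_floor_ug_min Rate magnitude (ug/min) below which a segment is
#'   considered flat for onset detection.
#' @return A one-row tibble: `start_mass_ug`, `ghost_mass_ug`,
#'   `ghost_fraction_pct`, `onset_time_min`, `completion_time_min`.
#' @export
compute_metrics <- function(series, segments, jumps = NULL,
                            dissolved_threshold_ug = 2.1,
                            rate_floor_ug_min = 0.05) {
  if (nrow(series) == 0) stop_insufficient("Empty mass series.")
  check_number(dissolved_threshold_ug, "dissolved_threshold_ug", positive = TRUE)
  in_seg <- function(seg) {
    series$time_min >= seg$t_start_min & series$time_min <= seg$t_end_min
  }
  # Robust mean (median) of a stable boundary segment; when the pellet is
  # already dissolving in that segment, the fitted line evaluated at the
  # boundary is the unbiased estimate instead.
  seg_boundary_mass <- function(seg, t_at) {
    if (abs(seg$rate_ug_min) <= rate_floor_ug_min) {
      median(series$mass_ug[in_seg(seg)])
    } else {
      seg$intercept_ug + seg$rate_ug_min * t_at
    }
  }
  first_seg <- segments[1, ]
  last_seg <- segments[nrow(segments), ]
  start_mass <- seg_boundary_mass(first_seg, first_seg$t_start_min)
  tail_mass <- median(tail(series$mass_ug, 5))
  ghost_mass <- if (tail_mass < dissolved_threshold_ug) 0 else
    seg_boundary_mass(last_seg, last_seg$t_end_min)
  ghost_fraction <- if (start_mass > 0) 100 * ghost_mass / start_mass else NA_real_
  active <- abs(segments$rate_ug_min) > rate_floor_ug_min
  onset_candidates <- c(
    segments$t_start_min[active],
    if (!is.null(jumps) && nrow(jumps) > 0) jumps$time_min else numeric()
  )
  onset <- if (length(onset_candidates) > 0) min(onset_candidates) else NA_real_
  below <- series$time_min[series$mass_ug < dissolved_threshold_ug]
  completion <- if (length(below) > 0) min(below) else NA_real_
  tibble(
    start_mass_ug = start_mass,
    ghost_mass_ug = ghost_mass,
    ghost_fraction_pct = ghost_fraction,
    onset_time_min = onset,
    completion_time_min = completion
  )
}

#' Fit a complete dissolution profile
#'
#' The full profile analysis: detect abrupt jump events, excise them, fit
#' piecewise-linear segments per inter-jump block, refine each jump's
#' magnitude against its flanking segment fits, and compute summary
#' metrics. Jumps are handled separately from segments because a sudden
#' 50 ug loss inside 10 s would otherwise dominate any slope fit.
#'
#' @param series A `mass_series` tibble (>= 3 points).
#' @param min_drop_ug Jump threshold (ug); default `max(10 * uncertainty, 5)`.
#' @param max_span_s Maximum jump duration (s); default 30.
#' @param max_segments,penalty,min_seg Passed to [segment_profile()]
#'   (applied per inter-jump block).
#' @param dissolved_threshold_ug Dissolved threshold. Default: the series'
#'   detection floor (smallest mass the peak-detection prominence can
#'   witness, when recorded) plus 3x the per-point uncertainty (mass
#'   resolution); falls back to 2.1 ug when neither is available.
#' @param rate_floor_ug_min Onset rate floor; see [compute_metrics()].
#' @return An object of class `dissolution_profile`: list with `series`,
#'   `segments`, `jumps`, `metrics` and the parameters used. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_dissolution_profile <- function(series, min_drop_ug = NULL,
                                    max_span_s = 30, max_segments = 6,
                                    penalty = NULL, min_seg = 3,
                                    dissolved_threshold_ug = NULL,
                                    rate_floor_ug_min = 0.05) {
  if (nrow(series) < 3) stop_insufficient("Need at least 3 mass points to fit a profile.")
  unc <- suppressWarnings(stats::median(series$uncertainty_ug, na.rm = TRUE))
  if (is.null(min_drop_ug)) {
    min_drop_ug <- if (is.finite(unc)) max(10 * unc, 5) else 5
  }
  if (is.null(dissolved_threshold_ug)) {
    floor_ug <- attr(series, "detection_floor_ug") %||% 0
    if (!is.finite(floor_ug)) floor_ug <- 0
    dissolved_threshold_ug <- if (is.finite(unc) && unc > 0) {
      floor_ug + 3 * unc
    } else if (floor_ug > 0) {
      2 * floor_ug
    } else 2.1
  }
  jumps <- detect_jumps(series, min_drop_ug = min_drop_ug, max_span_s = max_span_s)

  # Split the series into blocks between jump events and segment each.
  n <- nrow(series)
  cuts <- if (nrow(jumps) > 0) {
    rbind(cbind(jumps$row_start, jumps$row_end))
  } else matrix(numeric(0), ncol = 2)
  block_edges <- c(0L, as.vector(t(cuts)), n)
  seg_list <- list()
  for (b in seq_len(length(block_edges) / 2)) {
    i0 <- block_edges[2 * b - 1] + ifelse(b == 1, 1L, 0L)
    i1 <- block_edges[2 * b]
    block <- series[i0:i1, , drop = FALSE]
    if (nrow(block) < max(3, min_seg)) {
      # Too short to segment: fit one line (or a constant for 1-2 points).
      ft <- make_segment_fitter(block$time_min, block$mass_ug)(1L, nrow(block))
      seg_list[[b]] <- tibble(
        t_start_min = block$time_min[1], t_end_min = block$time_min[nrow(block)],
        rate_ug_min = ft$rate, intercept_ug = ft$intercept,
        n_points = ft$n, rss = ft$rss, rate_se = NA_real_
      )
    } else {
      seg_list[[b]] <- suppressWarnings(
        segment_profile(block, max_segments = max_segments,
                        penalty = penalty, min_seg = min_seg)
      )
    }
  }
  # Stitch block boundaries to the jump times so segments stay contiguous.
  if (nrow(jumps) > 0) {
    for (b in seq_len(nrow(jumps))) {
      seg_list[[b]]$t_end_min[nrow(seg_list[[b]])] <- jumps$time_min[b]
      seg_list[[b + 1]]$t_start_min[1] <- jumps$time_min[b]
    }
  }
  segments <- dplyr::bind_rows(seg_list)
  segments <- structure(segments, class = c("segment_table", class(tibble())))

  # Refine jump magnitudes against the flanking fitted lines.
  if (nrow(jumps) > 0) {
    for (b in seq_len(nrow(jumps))) {
      before <- seg_list[[b]][nrow(seg_list[[b]]), ]
      after <- seg_list[[b + 1]][1, ]
      jumps$dmass_ug[b] <- -refine_jump(jumps[b, ], series, before, after)
    }
  }

  metrics <- compute_metrics(
    series, segments, jumps,
    dissolved_threshold_ug = dissolved_threshold_ug,
    rate_floor_ug_min = rate_floor_ug_min
  )
  structure(
    list(
      series = series, segments = segments, jumps = jumps, metrics = metrics,
      params = list(
        min_drop_ug = min_drop_ug, max_span_s = max_span_s,
        max_segments = max_segments, penalty = penalty, min_seg = min_seg,
        dissolved_threshold_ug = dissolved_threshold_ug,
        rate_floor_ug_min = rate_floor_ug_min
      )
    ),
    class = "dissolution_profile"
  )
}

#' Mass-balance check for a fitted profile
#'
#' The mass lost between the starting mass and the ghost must be accounted
#' for by the detected jumps plus the rates integrated over their segments.
#' Returns the two sides of that balance, their difference, and an
#' aggregate uncertainty combining the start/ghost estimates, the segment
#' rate standard errors, the jump estimates, and (when the pellet dissolved
#' below the detection threshold) the unobserved terminal mass.
#'
#' @param profile A `dissolution_profile`.
#' @return One-row tibble: `observed_loss_ug`, `accounted_loss_ug`,
#'   `residual_ug`, `uncertainty_ug`, `z`.
#' @export
mass_balance <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  seg <- profile$segments
  met <- profile$metrics
  series <- profile$series
  unc <- suppressWarnings(stats::median(series$uncertainty_ug, na.rm = TRUE))
  if (!is.finite(unc) || unc == 0) unc <- robust_sd(diff(series$mass_ug)) / sqrt(2)
  observed <- met$start_mass_ug - met$ghost_mass_ug
  seg_loss <- sum(abs(seg$rate_ug_min) * (seg$t_end_min - seg$t_start_min))
  jump_loss <- if (nrow(profile$jumps) > 0) sum(abs(profile$jumps$dmass_ug)) else 0
  accounted <- seg_loss + jump_loss
  n1 <- seg$n_points[1]; n2 <- seg$n_points[nrow(seg)]
  u_start <- 1.2533 * unc / sqrt(max(1, n1))
  u_ghost <- if (met$ghost_mass_ug == 0) 0 else 1.2533 * unc / sqrt(max(1, n2))
  u_rates <- sqrt(sum(
    (dplyr::coalesce(seg$rate_se, unc) * (seg$t_end_min - seg$t_start_min))^2
  ))
  u_jumps <- if (nrow(profile$jumps) > 0) 2 * unc * sqrt(nrow(profile$jumps)) else 0
  # Across an excised jump gap the local trend is ambiguous between the
  # flanking rates; bound that discretization error by |r_b - r_a| * gap/2.
  u_disc <- 0
  if (nrow(profile$jumps) > 0) {
    for (b in seq_len(nrow(profile$jumps))) {
      tj <- profile$jumps$time_min[b]
      before <- seg[abs(seg$t_end_min - tj) < 1e-9, ]
      after <- seg[abs(seg$t_start_min - tj) < 1e-9, ]
      if (nrow(before) == 1 && nrow(after) == 1) {
        u_disc <- u_disc +
          abs(before$rate_ug_min - after$rate_ug_min) *
          (profile$jumps$span_s[b] / 60) / 2
      }
    }
  }
  u_trunc <- if (met$ghost_mass_ug == 0) {
    max(tail(series$mass_ug, 1), profile$params$dissolved_threshold_ug)
  } else 0
  # A changepoint is estimated on the data grid, so at each interior
  # boundary the flanking fitted lines disagree by |rate difference| times
  # the placement error. The observed line gap at the boundary measures
  # that artifact directly; at zero noise it is bounded by
  # |rate difference| * spacing / 2. Boundaries belonging to excised jumps
  # are covered by u_disc above.
  u_break <- 0
  if (nrow(seg) > 1) {
    dt_med <- median(diff(series$time_min))
    jump_times <- profile$jumps$time_min
    for (s in seq_len(nrow(seg) - 1)) {
      tb <- seg$t_end_min[s]
      if (length(jump_times) > 0 && any(abs(jump_times - tb) < 1e-9)) next
      dr <- abs(seg$rate_ug_min[s] - seg$rate_ug_min[s + 1])
      gap <- abs((seg$intercept_ug[s] + seg$rate_ug_min[s] * tb) -
                   (seg$intercept_ug[s + 1] + seg$rate_ug_min[s + 1] * tb))
      u_break <- u_break + max(dr * dt_med / 2, gap)
    }
  }
  uncertainty <- sqrt(u_start^2 + u_ghost^2 + u_rates^2 + u_jumps^2) +
    u_trunc + u_disc + u_break
  tibble(
    observed_loss_ug = observed,
    accounted_loss_ug = accounted,
    residual_ug = observed - accounted,
    uncertainty_ug = uncertainty,
    z = (observed - accounted) / uncertainty
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("<dissolution_profile>\n")
  cat(sprintf("  points: %d, segments: %d, jumps: %d\n",
              nrow(x$series), nrow(x$segments), nrow(x$jumps)))
  m <- x$metrics
  cat(sprintf("  start %.2f ug, ghost %.2f ug (%.1f%%)\n",
              m$start_mass_ug, m$ghost_mass_ug, m$ghost_fraction_pct))
  cat(sprintf("  onset %s min, completion %s min\n",
              format(round(m$onset_time_min, 2)),
              format(round(m$completion_time_min, 2))))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  segment %d: %.2f-%.2f min at %.3g ug/min\n",
                i, s$t_start_min, s$t_end_min, s$rate_ug_min))
  }
  if (nrow(x$jumps) > 0) {
    for (i in seq_len(nrow(x$jumps))) {
      j <- x$jumps[i, ]
      cat(sprintf("  jump %d: %.3g ug at %.2f min (within %.0f s)\n",
                  i, j$dmass_ug, j$time_min, j$span_s))
    }
  }
  invisible(x)
}
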