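# Internal helpers shared across modules.

MICROGRAMS_PER_GRAM <- 1e6

stop_invalid <- function(msg) abort(msg, class = "pm_invalid_input")
stop_degenerate <- function(msg) abort(msg, class = "pm_degenerate")
stop_inconsistent <- function(msg) abort(msg, class = "pm_inconsistent")
stop_insufficient <- function(msg) abort(msg, class = "pm_insufficient_data")

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    stop_invalid(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

# Robust SD from the median absolute deviation; 0-safe.
robust_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0)
  stats::mad(x)
}

odd_window <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

format_num <- function(x) sprintf("%.12e", x)
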