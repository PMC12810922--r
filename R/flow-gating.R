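#' Debris gate on forward scatter
#'
#' Genuine cells fall on the FSC-A ~ FSC-H diagonal; dirt and agar fragments
#' do not. Events whose height/area ratio lies outside `ratio_band` are
#' removed before any fluorescence analysis. The removed count is attached
#' to the returned table so downstream classification can report fractions
#' of post-debris events.
#'
#' @param events a flow event table with columns `fsc_a`, `fsc_h`, `fl1`.
#' @param ratio_band inclusive `(lo, hi)` bounds on fsc_h/fsc_a.
#' @return The retained events, with attributes `n_removed` and `n_input`.
#' @export
gate_scatter <- function(events, ratio_band = c(0.7, 1.3)) {
  stopifnot(is.data.frame(events),
            all(c("fsc_a", "fsc_h", "fl1") %in% names(events)))
  if (nrow(events) == 0L) stop("empty event table")
  stopifnot(length(ratio_band) == 2L, ratio_band[1] <= ratio_band[2])
  ratio <- events$fsc_h / events$fsc_a
  keep <- ratio >= ratio_band[1] & ratio <= ratio_band[2]
  if (!any(keep)) {
    stop("scatter gate removed every event; degenerate sample or band")
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flow_event_table", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_input") <- length(keep)
  out
}

#' Kernel density estimate of the fluorescence channel
#'
#' Gaussian-kernel density of log10 fluorescence on a 512-point grid
#' extending 3 bandwidths past the data range. `"auto"` bandwidth is
#' Silverman's rule of thumb on the log10 values. The profile is
#' renormalized so that it integrates to 1 (trapezoid rule) exactly.
#'
#' @param fl1 positive fluorescence intensities (>= 50 events).
#' @param bandwidth `"auto"` or a positive bandwidth in log10 units.
#' @return Object of class `kde_profile` with fields `grid`, `density`,
#'   `bandwidth`.
#' @export
estimate_kde <- function(fl1, bandwidth = "auto") {
  if (is.data.frame(fl1)) fl1 <- fl1$fl1
  if (length(fl1) < 50L) stop("at least 50 events are required for a KDE")
  if (any(!is.finite(fl1)) || any(fl1 <= 0)) {
    stop("fluorescence intensities must be finite and strictly positive")
  }
  x <- log10(fl1)
  bw <- if (identical(bandwidth, "auto")) {
    stats::bw.nrd0(x)
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0) {
      stop("bandwidth must be \"auto\" or a positive number")
    }
    bandwidth
  }
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = 512L, cut = 3)
  area <- trapezoid_area(d$x, d$y)
  structure(list(grid = d$x, density = d$y / area, bandwidth = bw),
            class = "kde_profile")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Locate the two major peaks and the interpeak valley
#'
#' Finds local maxima of the density profile, ranks them by topographic
#' prominence, and keeps the two most prominent provided each clears
#' `min_prominence_fraction` of the maximum density. The valley is the
#' global minimum of the density strictly between the two peaks. A profile
#' with fewer than two qualifying peaks signals a unimodal sample
#' (condition class `mitofast_unimodal`); callers should fall back to
#' [dark_fraction_control()] in that case.
#'
#' @param profile a `kde_profile`.
#' @param min_prominence_fraction minimum peak prominence as a fraction of
#'   the maximum density (default 0.05).
#' @return Object of class `peak_valley` with fields `peak_lo`, `peak_hi`,
#'   `valley` (log10 positions) and `interpeak_distance`.
#' @export
locate_peaks_valley <- function(profile, min_prominence_fraction = 0.05) {
  stopifnot(inherits(profile, "kde_profile"))
  y <- profile$density
  g <- profile$grid
  idx <- local_maxima(y)
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence_fraction * max(y)
  if (sum(keep) < 2L) {
    stop(structure(
      class = c("mitofast_unimodal", "error", "condition"),
      list(message = paste0(
        "fewer than two peaks above the prominence threshold; ",
        "sample looks unimodal - use dark_fraction_control() instead"),
        call = sys.call(-1))))
  }
  idx <- idx[keep][order(prom[keep], decreasing = TRUE)][1:2]
  idx <- sort(idx)
  if (idx[2] - idx[1] < 2L) stop("major peaks are adjacent on the grid")
  between <- seq(idx[1] + 1L, idx[2] - 1L)
  v <- between[which.min(y[between])]
  structure(list(peak_lo = g[idx[1]], peak_hi = g[idx[2]], valley = g[v],
                 interpeak_distance = g[idx[2]] - g[idx[1]]),
            class = "peak_valley")
}

# indices of strict-left / weak-right local maxima (plateaus collapse to
# their leftmost point); endpoints are never peaks
local_maxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence: height above the higher of the two key saddles
# (minimum between the peak and the nearest higher ground on each side;
# the profile edge counts as ground level on a side with no higher point)
peak_prominence <- function(y, i) {
  left <- y[seq_len(i - 1L)]
  right <- y[seq(i + 1L, length(y))]
  base_left <- if (any(left > y[i])) {
    j <- max(which(left > y[i]))
    min(left[seq(j, length(left))])
  } else min(left)
  base_right <- if (any(right > y[i])) {
    j <- min(which(right > y[i]))
    min(right[seq_len(j)])
  } else min(right)
  y[i] - max(base_left, base_right)
}

#' Classify events into dark, heteroplasmic and fluorescent fractions
#'
#' The heteroplasmic window is centred on the interpeak valley with
#' half-width `window_frac` of the interpeak distance (default +/-10%), on
#' the log10 fluorescence axis. Events below the window are dark, events
#' inside (bounds inclusive) heteroplasmic, events above fluorescent.
#' Fractions are reported over post-debris events; if `events` came from
#' [gate_scatter()] the removed-event count is carried into the result.
#'
#' @param events gated flow event table.
#' @param pv a `peak_valley` from [locate_peaks_valley()].
#' @param window_frac half-width of the heteroplasmic window as a fraction
#'   of the interpeak distance.
#' @return Object of class `gating_result` with counts `n_total`,
#'   `n_debris`, `n_dark`, `n_het`, `n_fluor`, fractions `f_dark`, `f_het`,
#'   `f_fluor`, and the window bounds `window_lo`, `window_hi`.
#' @export
classify_events <- function(events, pv, window_frac = 0.10) {
  stopifnot(is.data.frame(events), inherits(pv, "peak_valley"),
            window_frac > 0)
  if (nrow(events) == 0L) stop("empty event table")
  d <- pv$interpeak_distance
  lo <- pv$valley - window_frac * d
  hi <- pv$valley + window_frac * d
  if (lo < pv$peak_lo || hi > pv$peak_hi) {
    stop("heteroplasmic window extends beyond a peak; peaks too close ",
         "for the requested window_frac")
  }
  x <- log10(events$fl1)
  n_dark <- sum(x < lo)
  n_het <- sum(x >= lo & x <= hi)
  n_fluor <- sum(x > hi)
  n_kept <- nrow(events)
  n_debris <- attr(events, "n_removed")
  if (is.null(n_debris)) n_debris <- 0L
  structure(
    list(n_total = n_kept + n_debris, n_debris = n_debris,
         n_dark = n_dark, n_het = n_het, n_fluor = n_fluor,
         f_dark = n_dark / n_kept, f_het = n_het / n_kept,
         f_fluor = n_fluor / n_kept,
         window_lo = lo, window_hi = hi),
    class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf(
    "FAST gating: %d events (%d debris removed)\n", x$n_total, x$n_debris))
  cat(sprintf("  dark          %6d  (%5.1f%%)\n", x$n_dark, 100 * x$f_dark))
  cat(sprintf("  heteroplasmic %6d  (%5.2f%%)\n", x$n_het, 100 * x$f_het))
  cat(sprintf("  fluorescent   %6d  (%5.1f%%)\n", x$n_fluor, 100 * x$f_fluor))
  cat(sprintf("  window [%.3f, %.3f] log10 units\n", x$window_lo, x$window_hi))
  invisible(x)
}

#' Dark fraction against a non-fluorescent control
#'
#' For unimodal samples the two-peak classifier is undefined; instead the
#' dark fraction is read against a non-fluorescent control strain: the
#' threshold is a high quantile of the control's fluorescence and the
#' returned value is the fraction of sample events at or below it.
#'
#' @param events gated sample events.
#' @param dark_control gated events of the non-fluorescent control strain.
#' @param quantile control quantile used as the darkness threshold
#'   (default 0.999, i.e. a 0.1% false-positive floor).
#' @return Fraction of `events` at or below the control threshold.
#' @export
dark_fraction_control <- function(events, dark_control, quantile = 0.999) {
  stopifnot(is.data.frame(events), is.data.frame(dark_control),
            quantile > 0, quantile < 1)
  if (nrow(dark_control) == 0L) stop("empty dark control")
  if (nrow(events) == 0L) stop("empty event table")
  thr <- stats::quantile(dark_control$fl1, quantile, names = FALSE)
  mean(events$fl1 <= thr)
}
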