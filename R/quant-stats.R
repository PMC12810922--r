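#' Exponential growth rate and doubling time from an OD600 curve
#'
#' Ordinary least squares on (time, ln OD). With `window = "auto"` the fit
#' is restricted to the exponential phase, found as the contiguous stretch
#' of points with OD between twice the initial reading and half the curve
#' maximum that maximizes r-squared; if no such stretch has at least 4
#' points the whole curve is used. Doubling time is `ln(2) / rate`.
#'
#' @param curve data frame with columns `time_h`, `od`.
#' @param window `"auto"` or explicit `(t_start, t_end)` in hours.
#' @return Object of class `growth_fit`: `rate` (per hour),
#'   `doubling_time` (hours), `window`, `r_squared`.
#' @export
fit_growth_rate <- function(curve, window = "auto") {
  stopifnot(is.data.frame(curve), all(c("time_h", "od") %in% names(curve)))
  t <- curve$time_h
  od <- curve$od
  if (any(od <= 0)) stop("OD values must be positive")
  if (identical(window, "auto")) {
    idx <- auto_exp_window(t, od)
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    idx <- which(t >= window[1] & t <= window[2])
  }
  if (length(idx) < 4L) stop("fewer than 4 points in the fit window")
  fit <- stats::lm(log(od[idx]) ~ t[idx])
  rate <- unname(stats::coef(fit)[2])
  if (rate <= 0) stop("non-positive growth rate; curve is not growing")
  structure(list(rate = rate, doubling_time = log(2) / rate,
                 window = c(t_start = min(t[idx]), t_end = max(t[idx])),
                 r_squared = r_squared(fit)),
            class = "growth_fit")
}

# plain coefficient of determination; exact fits give 1 without the
# summary.lm() perfect-fit warning
r_squared <- function(fit) {
  y <- fit$model[[1]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

# indices of the contiguous exponential-phase stretch maximizing r^2
auto_exp_window <- function(t, od) {
  eligible <- od >= 2 * od[1] & od <= max(od) / 2
  if (sum(eligible) < 4L) return(seq_along(t))
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- seq_along(t)
  best_r2 <- -Inf
  for (k in which(r$values & r$lengths >= 4L)) {
    idx <- starts[k]:ends[k]
    r2 <- r_squared(stats::lm(log(od[idx]) ~ t[idx]))
    if (r2 > best_r2) {
      best_r2 <- r2
      best <- idx
    }
  }
  best
}

#' Doubling time from initial and final cell counts
#'
#' For microcolonies grown on plates the doubling time follows from the
#' seeded and harvested cell counts: `T_d = hours * ln(2) / ln(nf / n0)`.
#'
#' @param n0 initial cell count (> 0).
#' @param nf final cell count (> `n0`).
#' @param hours growth duration in hours.
#' @return Doubling time in hours.
#' @export
plate_doubling_time <- function(n0, nf, hours) {
  stopifnot(n0 > 0, hours > 0)
  if (nf <= n0) stop("final count must exceed initial count")
  hours * log(2) / log(nf / n0)
}

#' Fluorescence decay half-life
#'
#' Fits an exponential decay to log-transformed fluorescence medians over
#' time by ordinary least squares and returns `ln(2) / (-slope)` in hours.
#'
#' @param series data frame with columns `time_h`, `median_fl` (positive),
#'   at least 3 points.
#' @return Half-life in hours.
#' @export
fit_half_life <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "median_fl") %in% names(series)))
  if (nrow(series) < 3L) stop("at least 3 time points are required")
  if (any(series$median_fl <= 0)) stop("medians must be positive")
  fit <- stats::lm(log(series$median_fl) ~ series$time_h)
  s <- unname(stats::coef(fit)[2])
  if (s >= 0) stop("series is not decaying; cannot fit a half-life")
  log(2) / (-s)
}

#' Relative mtDNA copy number from qPCR Cq values
#'
#' Per replicate, mtDNA abundance is the COX1:ACT1 ratio at perfect
#' amplification efficiency, `2^(Cq_ACT1 - Cq_COX1)`; per strain, the mean
#' over replicates; relative copy number is the strain mean divided by the
#' reference strain's mean (the reference maps to exactly 1).
#'
#' @param table data frame with columns `strain`, `target` (`"ACT1"` /
#'   `"COX1"`), `replicate`, `cq`.
#' @param reference_strain name of the reference strain.
#' @param efficiency amplification factor per cycle (default 2).
#' @return Named numeric vector of relative copy numbers.
#' @export
qpcr_relative_cn <- function(table, reference_strain, efficiency = 2) {
  stopifnot(is.data.frame(table),
            all(c("strain", "target", "replicate", "cq") %in% names(table)),
            efficiency > 1)
  if (!reference_strain %in% table$strain) {
    stop("reference strain not present in the table")
  }
  wide <- merge(
    table[table$target == "ACT1", c("strain", "replicate", "cq")],
    table[table$target == "COX1", c("strain", "replicate", "cq")],
    by = c("strain", "replicate"), suffixes = c("_act1", "_cox1"))
  n_pairs <- table(table$strain, table$target)
  if (any(n_pairs[, "ACT1"] != n_pairs[, "COX1"])) {
    stop("every (strain, replicate) needs both an ACT1 and a COX1 Cq")
  }
  wide$abundance <- efficiency^(wide$cq_act1 - wide$cq_cox1)
  means <- tapply(wide$abundance, wide$strain, mean)
  out <- means / means[[reference_strain]]
  out[reference_strain] <- 1
  out[order(names(out))]
}

#' Relative growth factor from a post-growth mixing fraction
#'
#' Equal numbers of founder cells of two strains grow exponentially for `G`
#' reference generations; the observed fraction `f_dark` of the
#' slower/faster strain then implies its growth-rate ratio
#' `g = 1 + log2(f_dark / (1 - f_dark)) / G`.
#'
#' @param f_dark observed fraction of the competing (non-fluorescent)
#'   strain, strictly between 0 and 1.
#' @param generations number of reference-strain generations `G` (> 0),
#'   e.g. total time divided by the reference doubling time.
#' @return Growth-rate ratio `g_other`.
#' @export
infer_growth_factor <- function(f_dark, generations) {
  stopifnot(generations > 0)
  if (f_dark <= 0 || f_dark >= 1) stop("f_dark must be strictly in (0, 1)")
  1 + log2(f_dark / (1 - f_dark)) / generations
}

#' Monte-Carlo resampling p-value against a simulated null
#'
#' Draws `B` values with replacement from the simulated distribution and
#' computes a one-sided empirical p-value with the add-one estimator
#' `p = (1 + #extreme) / (B + 1)` (never exactly zero, so Fisher
#' combination stays finite). With the default alternative
#' `"sim_exceeds_obs"`, draws at or below the observed value count as
#' extreme: a small p means the observation lies below the simulation
#' distribution.
#'
#' @param observed observed fraction.
#' @param sim_values per-run simulated values (>= 2 distinct).
#' @param B number of resampling draws (>= 100; default 10000).
#' @param seed optional integer seed.
#' @param alternative `"sim_exceeds_obs"` (default) or `"obs_exceeds_sim"`.
#' @return Empirical one-sided p-value in (0, 1].
#' @export
mc_pvalue <- function(observed, sim_values, B = 10000L, seed = NULL,
                      alternative = c("sim_exceeds_obs", "obs_exceeds_sim")) {
  alternative <- match.arg(alternative)
  if (length(sim_values) == 0L) stop("empty simulation values")
  if (length(unique(sim_values)) < 2L) {
    stop("at least 2 distinct simulation values are required")
  }
  if (B < 100L) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  draws <- sample(sim_values, B, replace = TRUE)
  extreme <- if (alternative == "sim_exceeds_obs") {
    sum(draws <= observed)
  } else {
    sum(draws >= observed)
  }
  (1 + extreme) / (B + 1)
}

#' Combine replicate p-values with Fisher's method
#'
#' `-2 * sum(log(p))` follows a chi-square distribution with `2k` degrees
#' of freedom under the joint null; the combined p-value is its upper tail.
#'
#' @param pvals replicate-level p-values, each in (0, 1].
#' @return Object of class `mc_test_result`: `pvalues`, `fisher_stat`,
#'   `df`, `combined_p`.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  stat <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  structure(list(pvalues = pvals, fisher_stat = stat, df = df,
                 combined_p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mc_test_result")
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat(sprintf(
    "Fisher combination of %d p-values: chi2(%d) = %.3f, p = %.4g %s\n",
    length(x$pvalues), x$df, x$fisher_stat, x$combined_p,
    significance_stars(x$combined_p)))
  invisible(x)
}

# significance tiers used in the figure legends
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else ""
}
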