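test_that("scatter gate keeps diagonal events and rejects planted debris", {
  ev <- data.frame(fsc_a = rep(1e5, 10), fsc_h = rep(1e5, 10), fl1 = 1:10)
  g <- gate_scatter(ev)
  expect_equal(nrow(g), 10)
  expect_equal(attr(g, "n_removed"), 0L)

  spec <- het_mixture_spec(10000, debris_fraction = 0.10)
  mix <- make_flow_mixture(spec, seed = 2)
  g <- gate_scatter(mix)
  removed <- mix[!seq_len(nrow(mix)) %in% which(
    mix$fsc_h / mix$fsc_a >= 0.7 & mix$fsc_h / mix$fsc_a <= 1.3), ]
  # >= 99% of debris removed, <= 1% of genuine cells removed
  n_debris <- sum(mix$truth_label == "debris")
  expect_gte(sum(removed$truth_label == "debris") / n_debris, 0.99)
  expect_lte(sum(g$truth_label == "debris") / nrow(g), 0.001)
  n_cells <- sum(mix$truth_label != "debris")
  expect_lte(sum(removed$truth_label != "debris") / n_cells, 0.01)

  # degenerate band removes everything -> error
  expect_error(gate_scatter(mix, ratio_band = c(1, 1)), "every event")
  expect_error(gate_scatter(mix[0, ]), "empty")
})

test_that("KDE is normalized, consistent, and validates its inputs", {
  set.seed(5)
  fl1 <- 10^rnorm(10000, 3, 0.4)
  kde <- estimate_kde(fl1)
  area <- sum(diff(kde$grid) *
                (kde$density[-1] + kde$density[-length(kde$density)]) / 2)
  expect_equal(area, 1, tolerance = 1e-9)
  # profile mode within 0.05 log10 units of the true mean
  expect_lt(abs(kde$grid[which.max(kde$density)] - 3), 0.05)
  # grid covers data range plus 3 bandwidths
  expect_lte(kde$grid[1], min(log10(fl1)) - 3 * kde$bandwidth + 1e-9)
  expect_gte(kde$grid[512], max(log10(fl1)) + 3 * kde$bandwidth - 1e-9)
  expect_error(estimate_kde(fl1[1:10]), "50")
  expect_error(estimate_kde(c(fl1, -1)), "positive")
  expect_error(estimate_kde(fl1, bandwidth = 0), "bandwidth")
})

test_that("peak/valley detection finds a symmetric mixture's landmarks", {
  comps <- data.frame(name = c("lo", "hi"), fraction = c(0.5, 0.5),
                      mean_log10 = c(2, 4), sd_log10 = c(0.25, 0.25))
  ev <- make_flow_mixture(mixture_spec(comps, 10000), seed = 3)
  pv <- locate_peaks_valley(estimate_kde(ev$fl1))
  expect_lt(abs(pv$peak_lo - 2), 0.1)
  expect_lt(abs(pv$peak_hi - 4), 0.1)
  expect_lt(abs(pv$valley - 3), 0.15)
  expect_equal(pv$interpeak_distance, pv$peak_hi - pv$peak_lo)
  expect_true(pv$peak_lo < pv$valley && pv$valley < pv$peak_hi)
})

test_that("unimodal samples raise the dedicated condition", {
  set.seed(8)
  fl1 <- 10^rnorm(5000, 3, 0.3)
  expect_error(locate_peaks_valley(estimate_kde(fl1)),
               class = "mitofast_unimodal")
})

test_that("a small middle bump below prominence does not displace the majors", {
  # planted intermediate population is a minor bump between the major peaks
  ev <- make_flow_mixture(het_mixture_spec(10000), seed = 4)
  pv <- locate_peaks_valley(estimate_kde(ev$fl1))
  expect_lt(abs(pv$peak_lo - 2), 0.15)
  expect_lt(abs(pv$peak_hi - 4), 0.15)
})

test_that("classification window follows the +/-10% definition", {
  pv <- structure(list(peak_lo = 2, peak_hi = 4, valley = 3,
                       interpeak_distance = 2), class = "peak_valley")
  ev <- data.frame(fsc_a = 1, fsc_h = 1,
                   fl1 = 10^c(2.5, 2.79, 2.8, 3.0, 3.2, 3.21, 3.9))
  gr <- classify_events(ev, pv)
  expect_equal(c(gr$window_lo, gr$window_hi), c(2.8, 3.2))
  expect_equal(gr$n_dark, 2)   # below 2.8
  expect_equal(gr$n_het, 3)    # 2.8, 3.0, 3.2 inclusive
  expect_equal(gr$n_fluor, 2)  # above 3.2
  expect_equal(gr$f_dark + gr$f_het + gr$f_fluor, 1, tolerance = 1e-12)
  # all events below the valley
  lo <- data.frame(fsc_a = 1, fsc_h = 1, fl1 = 10^runif(50, 1, 2.5))
  gr <- classify_events(lo, pv)
  expect_equal(gr$f_dark, 1)
  expect_equal(gr$f_het + gr$f_fluor, 0)
  # window wider than the peak spacing is rejected
  expect_error(classify_events(ev, pv, window_frac = 0.6), "window")
})

test_that("planted three-population fractions are recovered end to end", {
  spec <- het_mixture_spec(10000, debris_fraction = 0.05)
  ev <- gate_scatter(make_flow_mixture(spec, seed = 11))
  pv <- locate_peaks_valley(estimate_kde(ev$fl1))
  gr <- classify_events(ev, pv)
  f <- spec$components$fraction
  expect_lt(abs(gr$f_dark - f[1]), 0.02)
  expect_lt(abs(gr$f_het - f[2]), 0.01)
  expect_lt(abs(gr$f_fluor - f[3]), 0.02)
})

test_that("classification is exhaustive, shift-equivariant and monotone", {
  spec <- het_mixture_spec(5000)
  ev <- make_flow_mixture(spec, seed = 21)
  kde <- estimate_kde(ev$fl1)
  pv <- locate_peaks_valley(kde)
  gr <- classify_events(ev, pv)
  expect_equal(gr$n_dark + gr$n_het + gr$n_fluor, gr$n_total - gr$n_debris)

  # multiplying fl1 by a constant shifts landmarks by log10(c), fractions fixed
  c0 <- 37
  ev2 <- ev
  ev2$fl1 <- ev$fl1 * c0
  pv2 <- locate_peaks_valley(estimate_kde(ev2$fl1, bandwidth = kde$bandwidth))
  expect_equal(pv2$peak_lo, pv$peak_lo + log10(c0), tolerance = 0.02)
  expect_equal(pv2$valley, pv$valley + log10(c0), tolerance = 0.02)
  gr2 <- classify_events(ev2, pv2)
  expect_equal(gr2$f_dark, gr$f_dark, tolerance = 0.01)
  expect_equal(gr2$f_het, gr$f_het, tolerance = 0.005)

  # widening the window never decreases the heteroplasmic fraction
  fr <- vapply(c(0.02, 0.05, 0.10, 0.15, 0.20),
               function(w) classify_events(ev, pv, w)$f_het, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("fractions equal brute-force counting against the window bounds", {
  spec <- het_mixture_spec(800)
  ev <- make_flow_mixture(spec, seed = 31)
  pv <- locate_peaks_valley(estimate_kde(ev$fl1))
  gr <- classify_events(ev, pv)
  x <- log10(ev$fl1)
  expect_identical(gr$n_dark, sum(x < gr$window_lo))
  expect_identical(gr$n_het, sum(x >= gr$window_lo & x <= gr$window_hi))
  expect_identical(gr$n_fluor, sum(x > gr$window_hi))
})

test_that("dark fractions are read against a non-fluorescent control", {
  ctrl <- dark_spike_events(5000, 1, seed = 41)  # all dark
  # planted 1.9% dark among fluorescent cells
  ev <- dark_spike_events(10000, 0.019, seed = 42)
  expect_lt(abs(dark_fraction_control(ev, ctrl) - 0.019), 0.005)
  # planted 0% -> at most the quantile's false-positive floor
  ev0 <- dark_spike_events(10000, 0, seed = 43)
  expect_lte(dark_fraction_control(ev0, ctrl), 0.002)
  # planted 7.4%
  ev7 <- dark_spike_events(10000, 0.074, seed = 44)
  expect_lt(abs(dark_fraction_control(ev7, ctrl) - 0.074), 0.008)
  expect_error(dark_fraction_control(ev, ctrl[0, ]), "empty")
})
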