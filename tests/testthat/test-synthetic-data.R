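test_that("single-component mixtures reproduce their planted parameters", {
  comps <- data.frame(name = "only", fraction = 1,
                      mean_log10 = 3, sd_log10 = 0.25)
  ev <- make_flow_mixture(mixture_spec(comps, 1000), seed = 1)
  expect_equal(nrow(ev), 1000)
  expect_true(all(ev$truth_label == "only"))
  expect_true(all(ev$fl1 > 0 & ev$fsc_a > 0 & ev$fsc_h > 0))
  # empirical log10 mean within 3 SE of the planted component mean
  se <- 0.25 / sqrt(1000)
  expect_lt(abs(mean(log10(ev$fl1)) - 3), 3 * se)
})

test_that("planted debris counts are binomial and land in the debris band", {
  spec <- het_mixture_spec(10000, debris_fraction = 0.10)
  ev <- make_flow_mixture(spec, seed = 7)
  ratio <- ev$fsc_h / ev$fsc_a
  in_band <- ratio >= 0.1 & ratio <= 0.6
  n_debris <- sum(ev$truth_label == "debris")
  expect_true(all(in_band[ev$truth_label == "debris"]))
  # Binomial(10000, 0.10) within 4 SD
  expect_lt(abs(n_debris - 1000), 4 * sqrt(10000 * 0.1 * 0.9))
  # non-debris cells sit on the diagonal
  expect_true(all(abs(ratio[ev$truth_label != "debris"] - 1) < 0.5))
})

test_that("mixture specs validate fractions and sizes", {
  comps <- data.frame(name = c("a", "b"), fraction = c(0.6, 0.5),
                      mean_log10 = c(2, 4), sd_log10 = c(0.2, 0.2))
  expect_error(mixture_spec(comps, 100), "sum to 1")
  comps$fraction <- c(0.5, 0.5)
  expect_error(mixture_spec(comps, 0), "n_events")
  expect_silent(mixture_spec(comps, 100))
})

test_that("identical spec and seed give byte-identical tables", {
  spec <- het_mixture_spec(500, debris_fraction = 0.05)
  expect_identical(make_flow_mixture(spec, seed = 9),
                   make_flow_mixture(spec, seed = 9))
  expect_identical(make_decay_series(100, 2.7, c(0, 2, 4, 6, 8),
                                     noise_sd_log = 0.05, seed = 4),
                   make_decay_series(100, 2.7, c(0, 2, 4, 6, 8),
                                     noise_sd_log = 0.05, seed = 4))
  expect_identical(
    make_qpcr_table(c(ref = 1, mut = 0.7), noise_sd = 0.1, seed = 2),
    make_qpcr_table(c(ref = 1, mut = 0.7), noise_sd = 0.1, seed = 2))
})

test_that("decay series follow the half-life definition", {
  s <- make_decay_series(100, 1, c(0, 1, 2))
  expect_equal(s$median_fl, c(100, 50, 25))
  expect_error(make_decay_series(100, 1, c(0, 2, 2)), "strictly increasing")
  expect_error(make_decay_series(100, -1, c(0, 1, 2)))
})

test_that("noisy decay series round-trip the half-life on average", {
  # parameter-recovery Monte Carlo: 1000 replicate fits, 2% tolerance
  hl <- vapply(1:1000, function(i) {
    fit_half_life(make_decay_series(100, 2.7, c(0, 2, 4, 6, 8),
                                    noise_sd_log = 0.05, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(hl) - 2.7) / 2.7, 0.02)
})

test_that("growth curves are exact exponentials when noiseless", {
  g <- make_growth_curve(0.1, log(2), 4)
  expect_equal(g$od[g$time_h == 1], 0.2)
  expect_equal(g$od[g$time_h == 3], 0.8)
  expect_equal(diff(g$time_h)[1], 1 / 3)  # 20-minute cadence
  expect_error(make_growth_curve(0.1, log(2), -1), "duration")
  # residuals of the log-linear fit vanish
  f <- fit_growth_rate(g)
  expect_equal(f$rate, log(2), tolerance = 1e-10)
})

test_that("qPCR generator plants recoverable copy-number ratios", {
  tab <- make_qpcr_table(c(ref = 1, a = 2, b = 0.71))
  cn <- qpcr_relative_cn(tab, "ref")
  expect_equal(unname(cn["a"]), 2)
  expect_equal(unname(cn["b"]), 0.71)
  # recovery Monte Carlo at noise_sd 0.1, 3x3 wells: within 10% in >= 95%
  ok <- vapply(1:500, function(i) {
    tab <- make_qpcr_table(c(ref = 1, mut = 0.71), noise_sd = 0.1,
                           replicates = 9, seed = i)
    abs(qpcr_relative_cn(tab, "ref")[["mut"]] - 0.71) / 0.71 < 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("vertex tables have the requested geometry and channels", {
  vt <- make_vertex_table(
    list(list(n_points = 11, spacing = 0.5),
         list(n_points = 5, spacing = 0.2, direction = c(0, 1, 0),
              origin = c(1, 1, 1))),
    channels = list(ch1 = 2, ch2 = function(x, y, z) x + 10),
    compartments = c("P1", "P2"))
  expect_equal(nrow(vt), 16)
  expect_equal(unique(vt$compartment[vt$line_id == 2]), "P2")
  d1 <- vt[vt$line_id == 1, ]
  expect_equal(sqrt(diff(d1$x)^2 + diff(d1$y)^2 + diff(d1$z)^2),
               rep(0.5, 10))
  expect_equal(vt$ch2, vt$x + 10)
  expect_error(make_vertex_table(list(), channels = list(a = 1)), "line")
})

test_that("tables survive the TSV round trip", {
  spec <- het_mixture_spec(200)
  ev <- make_flow_mixture(spec, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(ev, f)
  back <- read_flow_events(f)
  expect_equal(back$fl1, ev$fl1, tolerance = 1e-12)
  expect_equal(back$truth_label, ev$truth_label)
})

test_that("the event cap subsamples deterministically on read", {
  spec <- het_mixture_spec(300)
  ev <- make_flow_mixture(spec, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(ev, f)
  a <- read_flow_events(f, max_events = 100, seed = 5)
  b <- read_flow_events(f, max_events = 100, seed = 5)
  expect_equal(nrow(a), 100)
  expect_identical(a, b)
})
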