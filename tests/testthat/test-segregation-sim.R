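test_that("founder initialization hits the nearest achievable allele ratio", {
  set.seed(1)
  expect_equal(sum(init_founder(32, 0.1)$alleles), 3)    # round(32*0.1/1.1)
  expect_equal(sum(init_founder(32, 1)$alleles), 16)     # alternating intact
  expect_equal(sum(init_founder(32, 0.71)$alleles), 13)  # round(13.29)
  expect_equal(init_founder(32, 1)$alleles, rep(c(1L, 0L), 16))
  f <- init_founder(32, 0.1)
  expect_equal(f$h, 3 / 32)
  expect_equal(f$divisions_done, 0L)
  expect_error(init_founder(32, -0.1), ">= 0")
  expect_error(init_founder(31, 0.5), "even")
})

test_that("growth coupling is linear and the division probability clamps", {
  expect_equal(growth_rate_ratio(0, 0.93), 1)
  expect_equal(growth_rate_ratio(1, 0.93), 0.93)
  expect_equal(growth_rate_ratio(0.5, 0.98), 0.99)
  expect_equal(division_probability(1), 1)
  expect_equal(division_probability(0.93), 2^0.93 - 1)
  expect_equal(division_probability(1.03), 1)  # 2^1.03 - 1 clamped
  expect_error(growth_rate_ratio(1.5, 1), "0, 1")
  expect_error(division_probability(0), "positive")
})

test_that("division conserves alleles and replenishes both cells to N", {
  set.seed(7)
  for (i in 1:200) {
    cell <- init_founder(32, runif(1, 0.1, 1))
    d <- divide_cell(cell, nspl = 5)
    # conservation before replenishment
    expect_equal(sort(c(d$mother_presplit, d$daughter_presplit)),
                 sort(cell$alleles))
    expect_length(d$mother$alleles, 32)
    expect_length(d$daughter$alleles, 32)
    expect_equal(d$mother$divisions_done, 1L)
    expect_equal(d$daughter$divisions_done, 0L)
  }
  cell <- nucleoid_cell(rep(c(1L, 0L), 16), divisions_done = 11L)
  expect_error(divide_cell(cell, 5, ndau = 11), "post-replicative")
})

test_that("daughter heteroplasmy is unbiased at h = 0.5", {
  set.seed(11)
  cell <- nucleoid_cell(rep(c(1L, 0L), 16))
  hs <- vapply(1:10000, function(i) divide_cell(cell, 5)$daughter$h,
               numeric(1))
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - 0.5), 3 * se)
})

test_that("simulation runs are deterministic given config and seed", {
  cfg <- sim_config(ratio = 0.5, g_other = 0.98, ngen = 6L, n_runs = 3L,
                    seed = 99L)
  a <- run_replicates(cfg)
  b <- run_replicates(cfg)
  expect_identical(a$mean_h, b$mean_h)
  expect_identical(a$n_cells, b$n_cells)
})

test_that("neutral drift preserves expected heteroplasmy (martingale)", {
  # holds for any ngen/ndau/nspl; checked at a small horizon
  for (r in c(0.25, 0.5, 1)) {
    cfg <- sim_config(ratio = r, g_other = 1, ngen = 6L, n_runs = 200L)
    res <- run_replicates(cfg, seed = 17)
    h0 <- round(32 * r / (1 + r)) / 32
    se <- res$sd / sqrt(length(res$mean_h))
    expect_lt(abs(res$mean - h0), 3 * se + 1e-12)
  }
})

test_that("a growth handicap can only lower mean heteroplasmy", {
  cfg <- sim_config(ratio = 0.5, g_other = 0.93, ngen = 6L, n_runs = 200L)
  res <- run_replicates(cfg, seed = 23)
  h0 <- round(32 * 0.5 / 1.5) / 32
  se <- res$sd / sqrt(length(res$mean_h))
  expect_lt(res$mean, h0 + 3 * se)  # one-sided: no upward shift
  cfg$g_other <- 1
  res0 <- run_replicates(cfg, seed = 23)
  expect_lt(res$mean, res0$mean)  # handicap lowers the mean vs neutral
})

test_that("forced division doubles the population every generation", {
  # g_other = 1 gives p = 1: after 2 generations each founder made 4 cells
  cfg <- sim_config(ratio = 1, g_other = 1, ngen = 2L, n_founders = 5L,
                    n_runs = 1L)
  res <- simulate_population(cfg, seed = 5)
  expect_equal(res$n_cells, 5 * 4)
})

test_that("tiny instances match exact enumeration of division outcomes", {
  # N = 2, alleles (1, 0), nspl = 1: the single cut must fall between the
  # two nucleoids, one side gets allele 1, the other allele 0, each with
  # probability 1/2; replenishment duplicates the resident, so each output
  # cell is homoplasmic: h_daughter is 0 or 1 with probability 1/2 each.
  set.seed(29)
  cell <- nucleoid_cell(c(1L, 0L))
  hs <- vapply(1:50000, function(i) divide_cell(cell, 1)$daughter$h,
               numeric(1))
  expect_true(all(hs %in% c(0, 1)))
  # Binomial(50000, 1/2) within 4 SD
  expect_lt(abs(sum(hs) - 25000), 4 * sqrt(50000 * 0.25))
})

test_that("ratio sweeps are monotone in the founder ratio and matchable", {
  cfg <- sim_config(ratio = 0.5, g_other = 0.98, ngen = 6L)
  sw <- sweep_ratios(cfg, ratios = seq(0.2, 1, by = 0.2),
                     n_runs_per_ratio = 30L, seed = 31)
  # founder fraction rises with r; simulated means follow within MC noise
  expect_true(all(diff(sw$summary$mean_mean_h) > -0.02))
  expect_equal(best_match_ratio(sw, 0), 0.2)  # observed 0 -> smallest ratio
  expect_equal(best_match_ratio(sw, sw$summary$mean_mean_h[3]),
               sw$summary$ratio[3])
  expect_error(sweep_ratios(cfg, ratios = numeric(0)), "empty")
  expect_error(sweep_ratios(cfg, ratios = c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("configs validate their parameter ranges", {
  expect_error(sim_config(ratio = -1), "ratio")
  expect_error(sim_config(ratio = 0.5, g_other = 0), "g_other")
  expect_error(sim_config(ratio = 0.5, n_nucleoids = 7), "even")
  expect_error(sim_config(ratio = 0.5, nspl = 32), "nspl")
})
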