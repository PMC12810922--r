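#' Configuration of a nucleoid segregation simulation
#'
#' Bundles every parameter of the agent-based model. A simulated cell holds
#' `n_nucleoids` ordered mtDNA nucleoids, each carrying allele 0 (reference,
#' fluorescently labelled mtDNA) or 1 (the competing, non-fluorescent
#' variant). The population grows for `ngen` synchronous steps, each step
#' corresponding to one doubling time of the reference strain; a cell's
#' chance of dividing within a step falls with its heteroplasmy level when
#' the competing variant grows slower (`g_other < 1`).
#'
#' @param ratio mtDNA copy-number ratio other:reference carried into the
#'   founder (>= 0); the founder's variant fraction is `ratio / (1 + ratio)`.
#' @param g_other growth-rate ratio of the strain homoplasmic for the
#'   competing variant, relative to the reference strain (in (0, 2]).
#' @param n_nucleoids nucleoids per cell (even, >= 2; default 32).
#' @param ngen number of synchronous generations (default 14, spanning at
#'   least 20 h at the measured 1.48 h plate doubling time).
#' @param ndau replicative lifespan: maximum divisions per cell (default 11).
#' @param nspl number of cut points when the nucleoid string is partitioned
#'   at division (default 5; must be < `n_nucleoids`).
#' @param n_founders independent founder cells per run (default 30, the
#'   number of micromanipulated cells per experiment).
#' @param n_runs replicate runs for [run_replicates()] (default 100).
#' @param seed optional integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(ratio, g_other = 1, n_nucleoids = 32L, ngen = 14L,
                       ndau = 11L, nspl = 5L, n_founders = 30L,
                       n_runs = 100L, seed = NULL) {
  n_nucleoids <- as.integer(n_nucleoids)
  if (ratio < 0) stop("ratio must be >= 0")
  if (g_other <= 0 || g_other > 2) stop("g_other must be in (0, 2]")
  if (n_nucleoids < 2L || n_nucleoids %% 2L != 0L) {
    stop("n_nucleoids must be even and >= 2")
  }
  if (ngen < 1L) stop("ngen must be >= 1")
  if (ndau < 1L) stop("ndau must be >= 1")
  if (nspl < 1L || nspl >= n_nucleoids) stop("nspl must be in [1, N-1]")
  if (n_founders < 1L) stop("n_founders must be >= 1")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  structure(list(ratio = ratio, g_other = g_other,
                 n_nucleoids = n_nucleoids, ngen = as.integer(ngen),
                 ndau = as.integer(ndau), nspl = as.integer(nspl),
                 n_founders = as.integer(n_founders),
                 n_runs = as.integer(n_runs), seed = seed),
            class = "sim_config")
}

#' A single simulated cell
#'
#' @param alleles integer vector of 0/1 nucleoid alleles.
#' @param divisions_done divisions this cell has completed.
#' @return Object of class `nucleoid_cell` with fields `alleles`,
#'   `divisions_done` and the heteroplasmy level `h` (mean allele).
#' @export
nucleoid_cell <- function(alleles, divisions_done = 0L) {
  alleles <- as.integer(alleles)
  stopifnot(all(alleles %in% c(0L, 1L)), divisions_done >= 0L)
  structure(list(alleles = alleles,
                 divisions_done = as.integer(divisions_done),
                 h = mean(alleles)),
            class = "nucleoid_cell")
}

#' Initialize a founder cell from an mtDNA copy-number ratio
#'
#' The founder starts from the maximally interleaved string `[1,0,1,0,...]`;
#' randomly chosen positions are then flipped until the count of 1-alleles
#' equals `round(N * r / (1 + r))`, the nearest achievable match to the
#' requested other:reference ratio. With `N = 32` and `r = 0.1` this yields
#' 3 ones and 29 zeros.
#'
#' @param N nucleoids per cell (even, >= 2).
#' @param r mtDNA ratio other:reference (>= 0).
#' @return A [nucleoid_cell()] with `divisions_done = 0`.
#' @export
init_founder <- function(N, r) {
  N <- as.integer(N)
  if (N < 2L || N %% 2L != 0L) stop("N must be even and >= 2")
  if (r < 0) stop("r must be >= 0")
  alleles <- rep(c(1L, 0L), length.out = N)
  k <- round(N * r / (1 + r))
  ones <- sum(alleles)
  if (k < ones) {
    flip <- which(alleles == 1L)
    flip <- flip[sample.int(length(flip), ones - k)]
    alleles[flip] <- 0L
  } else if (k > ones) {
    flip <- which(alleles == 0L)
    flip <- flip[sample.int(length(flip), k - ones)]
    alleles[flip] <- 1L
  }
  nucleoid_cell(alleles, 0L)
}

#' Heteroplasmy-coupled growth rate and division probability
#'
#' `growth_rate_ratio()` interpolates linearly between the reference rate
#' (1 at `h = 0`) and the homoplasmic-variant rate (`g_other` at `h = 1`):
#' `g = 1 + (g_other - 1) * h`. `division_probability()` converts a relative
#' growth rate into the probability that a cell divides within one
#' simulation step (one reference doubling time):
#' `p = clamp(2^g - 1, 0, 1)`, so a reference-rate cell divides with
#' certainty each step.
#'
#' @param h heteroplasmy level(s) in `[0, 1]`.
#' @param g_other growth-rate ratio of the homoplasmic-variant strain.
#' @param g relative growth rate(s) (> 0).
#' @return Numeric vector of growth-rate ratios or division probabilities.
#' @export
growth_rate_ratio <- function(h, g_other) {
  if (any(h < 0 | h > 1)) stop("h must be in [0, 1]")
  1 + (g_other - 1) * h
}

#' @rdname growth_rate_ratio
#' @export
division_probability <- function(g) {
  if (any(g <= 0)) stop("g must be positive")
  pmin(1, pmax(0, 2^g - 1))
}

#' Divide one cell into mother and daughter
#'
#' The ordered nucleoid string is cut at `nspl` distinct, uniformly chosen
#' internal boundaries; the `nspl + 1` segments are distributed alternately
#' between mother and daughter, a fair coin deciding which side receives
#' the first segment. This mirrors the roughly even partitioning of
#' mitochondrial material between mother and bud while keeping mixing
#' limited to `nspl` cut points. Both cells then replenish to the full
#' complement in balanced rounds -- a uniformly chosen subset of resident
#' nucleoids (every resident while more copies are missing than residents
#' exist) is duplicated once, mirroring the roughly once-per-cell-cycle
#' replication of mtDNA. Each copy is inserted at a uniformly chosen
#' position in the string: between divisions the fused network's
#' fusion/fission dynamics reorder nucleoids, so a new copy's position is
#' not tied to its template's. Mother and daughter are exchangeable and
#' replenishment is unbiased, so expected heteroplasmy is conserved at
#' every division. The mother's division count increments; the daughter
#' starts at zero.
#'
#' @param cell a [nucleoid_cell()].
#' @param nspl number of cut points.
#' @param ndau optional replicative lifespan; dividing a cell with
#'   `divisions_done >= ndau` is an error.
#' @return List with elements `mother` and `daughter` (both
#'   `nucleoid_cell`), plus `mother_presplit` / `daughter_presplit`, the
#'   allele segments before replenishment (their concatenation is a
#'   permutation-free partition of the parent string).
#' @export
divide_cell <- function(cell, nspl = 5L, ndau = Inf) {
  stopifnot(inherits(cell, "nucleoid_cell"))
  if (cell$divisions_done >= ndau) {
    stop("cell is post-replicative (divisions_done >= ndau)")
  }
  res <- divide_cell_cpp(cell$alleles, as.integer(nspl))
  list(mother = nucleoid_cell(res$mother, cell$divisions_done + 1L),
       daughter = nucleoid_cell(res$daughter, 0L),
       mother_presplit = res$mother_presplit,
       daughter_presplit = res$daughter_presplit)
}

#' Simulate one population run
#'
#' Initializes `n_founders` independent founders via [init_founder()] and
#' iterates `ngen` synchronous steps; at each step every cell that has not
#' exhausted its replicative lifespan divides with probability
#' `division_probability(growth_rate_ratio(h, g_other))`. The run statistic
#' is the unweighted mean heteroplasmy over all cells present at the end.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (overrides `config$seed`).
#' @param keep_h if `TRUE`, also return the per-cell heteroplasmy values.
#' @return List with `mean_h`, `n_cells`, and optionally `h`.
#' @export
simulate_population <- function(config, seed = NULL, keep_h = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  founders <- t(vapply(seq_len(config$n_founders),
                       function(i) init_founder(config$n_nucleoids,
                                                config$ratio)$alleles,
                       integer(config$n_nucleoids)))
  simulate_run_cpp(founders, config$ngen, config$ndau, config$nspl,
                   config$g_other, keep_h)
}

#' Run replicate simulations
#'
#' Executes `config$n_runs` independent runs from a single seeded RNG
#' stream and summarizes the distribution of per-run mean heteroplasmy.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (overrides `config$seed`).
#' @return Object of class `sim_result`: `mean_h` (per-run values),
#'   `n_cells` (per-run final counts), `mean`, `sd`, and the `config`.
#' @export
run_replicates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  cfg <- config
  cfg$seed <- NULL  # runs share one RNG stream
  mean_h <- numeric(config$n_runs)
  n_cells <- numeric(config$n_runs)
  for (i in seq_len(config$n_runs)) {
    r <- simulate_population(cfg)
    mean_h[i] <- r$mean_h
    n_cells[i] <- r$n_cells
  }
  structure(list(mean_h = mean_h, n_cells = n_cells,
                 mean = mean(mean_h), sd = stats::sd(mean_h),
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "segregation simulation: %d runs, ratio %.3g, g_other %.3g\n",
    length(x$mean_h), x$config$ratio, x$config$g_other))
  cat(sprintf("  mean of mean_h = %.4f (sd %.4f)\n", x$mean, x$sd))
  cat(sprintf("  final cells per run: %.0f (median)\n",
              stats::median(x$n_cells)))
  invisible(x)
}

#' Sweep founder mtDNA ratios
#'
#' Repeats the simulation over a grid of founder ratios (default 0.10-1.00
#' in steps of 0.05, 10 runs each) and tabulates the distribution of mean
#' heteroplasmy per ratio. [best_match_ratio()] then returns the grid ratio
#' whose mean simulated dark-cell fraction lies closest to an observed
#' value.
#'
#' @param config a [sim_config()]; its `ratio` and `n_runs` are overridden
#'   per grid point.
#' @param ratios grid of ratios in (0, 1].
#' @param n_runs_per_ratio runs per grid point (default 10).
#' @param seed optional integer seed (overrides `config$seed`).
#' @return Object of class `ratio_sweep`: a data frame `runs` of
#'   (ratio, run, mean_h) and a data frame `summary` of per-ratio means/sds.
#' @export
sweep_ratios <- function(config, ratios = seq(0.10, 1.00, by = 0.05),
                         n_runs_per_ratio = 10L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(ratios) == 0L) stop("empty ratio grid")
  if (any(ratios <= 0 | ratios > 1)) stop("ratios must be in (0, 1]")
  if (!is.null(seed)) {
    set.seed(seed)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  rows <- lapply(ratios, function(r) {
    cfg <- config
    cfg$ratio <- r
    cfg$n_runs <- as.integer(n_runs_per_ratio)
    cfg$seed <- NULL
    mh <- numeric(cfg$n_runs)
    for (i in seq_len(cfg$n_runs)) mh[i] <- simulate_population(cfg)$mean_h
    data.frame(ratio = r, run = seq_len(cfg$n_runs), mean_h = mh)
  })
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$ratio), function(d) {
    data.frame(ratio = d$ratio[1], mean_mean_h = mean(d$mean_h),
               sd_mean_h = stats::sd(d$mean_h), n_runs = nrow(d))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, config = config),
            class = "ratio_sweep")
}

#' @rdname sweep_ratios
#' @param sweep a `ratio_sweep`.
#' @param observed_fraction observed dark-cell fraction to match.
#' @export
best_match_ratio <- function(sweep, observed_fraction) {
  stopifnot(inherits(sweep, "ratio_sweep"),
            observed_fraction >= 0, observed_fraction <= 1)
  d <- abs(sweep$summary$mean_mean_h - observed_fraction)
  sweep$summary$ratio[which.min(d)]  # ties: smallest grid ratio
}
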