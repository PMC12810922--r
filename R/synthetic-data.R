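#' Specify a synthetic flow-cytometry mixture
#'
#' Describes a log-normal mixture of cell populations plus a planted debris
#' fraction, the ground truth from which [make_flow_mixture()] draws event
#' tables. Fluorescence of each component is log-normal on the log10 scale
#' (the standard working model for cytometry channels); debris events sit off
#' the FSC-A ~ FSC-H diagonal, at a low height/area ratio.
#'
#' @param components data frame with columns `name`, `fraction`,
#'   `mean_log10`, `sd_log10`: one row per cell population. Fractions are of
#'   the non-debris (cell) events and must sum to 1 (tolerance 1e-9).
#' @param n_events total number of events to draw (cells + debris).
#' @param debris_fraction expected fraction of events that are debris, in
#'   `[0, 1)`.
#' @param fsc_mean_log10,fsc_sd_log10 log10-normal parameters of FSC-A.
#' @param debris_ratio_range range of the fsc_h/fsc_a ratio for debris
#'   events; cells scatter tightly around ratio 1.
#' @param cell_ratio_sd standard deviation of the fsc_h/fsc_a ratio for
#'   genuine cells (centred on 1).
#' @return An object of class `mixture_spec`.
#' @seealso [make_flow_mixture()], [het_mixture_spec()]
#' @export
mixture_spec <- function(components, n_events,
                         debris_fraction = 0,
                         fsc_mean_log10 = 5.7, fsc_sd_log10 = 0.08,
                         debris_ratio_range = c(0.1, 0.6),
                         cell_ratio_sd = 0.05) {
  stopifnot(is.data.frame(components),
            all(c("name", "fraction", "mean_log10", "sd_log10") %in%
                  names(components)))
  if (nrow(components) < 1L) {
    stop("at least one mixture component is required")
  }
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("component fractions must sum to 1 (tolerance 1e-9)")
  }
  if (any(components$fraction < 0)) stop("negative component fraction")
  if (any(components$sd_log10 < 0)) stop("negative component sd")
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L) stop("n_events must be >= 1")
  if (debris_fraction < 0 || debris_fraction >= 1) {
    stop("debris_fraction must be in [0, 1)")
  }
  stopifnot(length(debris_ratio_range) == 2L,
            debris_ratio_range[1] > 0,
            debris_ratio_range[1] < debris_ratio_range[2])
  structure(
    list(components = components, n_events = n_events,
         debris_fraction = debris_fraction,
         fsc_mean_log10 = fsc_mean_log10, fsc_sd_log10 = fsc_sd_log10,
         debris_ratio_range = debris_ratio_range,
         cell_ratio_sd = cell_ratio_sd),
    class = "mixture_spec")
}

#' Three-population mixture of dark, heteroplasmic and fluorescent cells
#'
#' Convenience constructor for the mixture observed in a segregation-tracking
#' experiment 20 h after mating: a non-fluorescent (dark) cluster, a
#' fluorescent cluster, and a small intermediate population of residual
#' heteroplasmic cells sitting at the interpeak valley.
#'
#' The intermediate component is centred midway between the two major
#' components on the log10 axis. Its default sd is 0.09 x the interpeak
#' distance, chosen so that most planted intermediates fall inside the
#' +/-10% heteroplasmic window around the valley while the population stays
#' broad enough not to displace the interpeak density minimum. The major
#' components default to sd 0.35 log10 units, typical of the cluster widths
#' seen on log-scaled cytometry axes.
#'
#' @param n_events number of events.
#' @param f_dark,f_het,f_fluor planted population fractions; they are
#'   normalized to sum to 1, so rounded percentages can be passed directly.
#' @param mean_dark,mean_fluor log10 fl1 means of the two major components.
#' @param sd_major log10 sd of the dark and fluorescent components.
#' @param sd_het log10 sd of the intermediate component; default
#'   `0.09 * (mean_fluor - mean_dark)`.
#' @param debris_fraction planted debris fraction (see [mixture_spec()]).
#' @param ... further arguments passed to [mixture_spec()].
#' @return A `mixture_spec` with components named `"dark"`, `"het"`,
#'   `"fluor"`.
#' @export
het_mixture_spec <- function(n_events,
                             f_dark = 0.509, f_het = 0.0332, f_fluor = 0.458,
                             mean_dark = 2, mean_fluor = 4,
                             sd_major = 0.35,
                             sd_het = 0.09 * (mean_fluor - mean_dark),
                             debris_fraction = 0, ...) {
  stopifnot(mean_fluor > mean_dark)
  f <- c(f_dark, f_het, f_fluor)
  if (any(f < 0) || sum(f) <= 0) stop("invalid population fractions")
  f <- f / sum(f)
  comps <- data.frame(
    name = c("dark", "het", "fluor"),
    fraction = f,
    mean_log10 = c(mean_dark, (mean_dark + mean_fluor) / 2, mean_fluor),
    sd_log10 = c(sd_major, sd_het, sd_major),
    stringsAsFactors = FALSE)
  mixture_spec(comps, n_events, debris_fraction = debris_fraction, ...)
}

#' Draw a synthetic flow-cytometry event table
#'
#' Samples events from a [mixture_spec()]: debris membership is Bernoulli
#' with the planted debris fraction, cell events are assigned to components
#' multinomially, and fl1 is log-normal per component. The returned table
#' carries the planted component in `truth_label` so downstream classifiers
#' can be scored against ground truth.
#'
#' @param spec a `mixture_spec`.
#' @param seed optional integer seed; when supplied the draw is fully
#'   reproducible.
#' @return A data frame of class `flow_event_table` with columns `fsc_a`,
#'   `fsc_h`, `fl1`, `truth_label` (`"debris"` or a component name).
#' @export
make_flow_mixture <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_events
  is_debris <- stats::runif(n) < spec$debris_fraction
  comp <- character(n)
  comp[is_debris] <- "debris"
  n_cells <- sum(!is_debris)
  if (n_cells > 0L) {
    comp[!is_debris] <- sample(spec$components$name, n_cells, replace = TRUE,
                               prob = spec$components$fraction)
  }
  fsc_a <- 10^stats::rnorm(n, spec$fsc_mean_log10, spec$fsc_sd_log10)
  ratio <- stats::rnorm(n, 1, spec$cell_ratio_sd)
  ratio[is_debris] <- stats::runif(sum(is_debris),
                                   spec$debris_ratio_range[1],
                                   spec$debris_ratio_range[2])
  fl1 <- numeric(n)
  for (k in seq_len(nrow(spec$components))) {
    idx <- comp == spec$components$name[k]
    fl1[idx] <- 10^stats::rnorm(sum(idx),
                                spec$components$mean_log10[k],
                                spec$components$sd_log10[k])
  }
  # debris autofluorescence: dim, below the darkest cell component
  if (any(is_debris)) {
    fl1[is_debris] <- 10^stats::rnorm(sum(is_debris),
                                      min(spec$components$mean_log10) - 0.5,
                                      0.4)
  }
  out <- data.frame(fsc_a = fsc_a, fsc_h = fsc_a * ratio, fl1 = fl1,
                    truth_label = comp, stringsAsFactors = FALSE)
  class(out) <- c("flow_event_table", "data.frame")
  out
}

#' Synthetic fluorescence decay time course
#'
#' Median fluorescence after halting synthesis (e.g. chloramphenicol
#' treatment) decays exponentially: `median(t) = i0 * 2^(-t / half_life)`,
#' optionally multiplied by log-normal noise.
#'
#' @param i0 initial median intensity (> 0).
#' @param half_life decay half-life in hours (> 0).
#' @param times sampling times in hours, non-negative and strictly
#'   increasing, at least 3 for downstream fitting.
#' @param noise_sd_log sd of multiplicative log-normal noise (natural-log
#'   scale); 0 gives a noiseless series.
#' @param seed optional integer seed.
#' @return Data frame of class `decay_series` with columns `time_h`,
#'   `median_fl`.
#' @export
make_decay_series <- function(i0, half_life, times, noise_sd_log = 0,
                              seed = NULL) {
  stopifnot(i0 > 0, half_life > 0, noise_sd_log >= 0)
  if (length(times) < 3L) stop("at least 3 time points are required")
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  med <- i0 * 2^(-times / half_life)
  if (noise_sd_log > 0) {
    med <- med * stats::rlnorm(length(times), 0, noise_sd_log)
  }
  out <- data.frame(time_h = times, median_fl = med)
  class(out) <- c("decay_series", "data.frame")
  out
}

#' Synthetic OD600 growth curve
#'
#' Exponential growth `od(t) = od0 * exp(rate * t)` sampled at plate-reader
#' intervals, with optional multiplicative log-normal noise.
#'
#' @param od0 starting OD600 (> 0).
#' @param rate exponential growth rate per hour (> 0).
#' @param duration_h total duration in hours (> 0).
#' @param interval_min sampling interval in minutes (default 20, the usual
#'   plate-reader cadence).
#' @param noise_sd_log sd of multiplicative log-normal noise.
#' @param seed optional integer seed.
#' @return Data frame of class `growth_curve` with columns `time_h`, `od`.
#' @export
make_growth_curve <- function(od0, rate, duration_h, interval_min = 20,
                              noise_sd_log = 0, seed = NULL) {
  stopifnot(od0 > 0, rate > 0, interval_min > 0, noise_sd_log >= 0)
  if (duration_h <= 0) stop("duration_h must be positive")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_h, by = interval_min / 60)
  od <- od0 * exp(rate * times)
  if (noise_sd_log > 0) od <- od * stats::rlnorm(length(times), 0, noise_sd_log)
  out <- data.frame(time_h = times, od = od)
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Synthetic qPCR Cq table with planted relative copy numbers
#'
#' Generates quantification-cycle values for a mitochondrial target (COX1)
#' and a nuclear reference (ACT1) under a perfect-efficiency model (factor 2
#' per cycle): `Cq_COX1 = Cq_ACT1 - log2(copy_number) + noise`. Replicate
#' noise is independent per well.
#'
#' @param strains named numeric vector of true COX1/ACT1 relative copy
#'   numbers (> 0), one per strain; include the reference strain (typically
#'   with copy number 1) so [qpcr_relative_cn()] can normalize.
#' @param base_cq_act1 mean ACT1 quantification cycle.
#' @param noise_sd sd of per-well Gaussian Cq noise (cycles).
#' @param replicates number of biological replicates per strain.
#' @param seed optional integer seed.
#' @return Data frame of class `qpcr_table` with columns `strain`, `target`,
#'   `replicate`, `cq`.
#' @export
make_qpcr_table <- function(strains, base_cq_act1 = 20, noise_sd = 0,
                            replicates = 3, seed = NULL) {
  stopifnot(is.numeric(strains), length(strains) >= 1L,
            !is.null(names(strains)), all(strains > 0),
            noise_sd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(strain = names(strains),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  cq_act1 <- base_cq_act1 + stats::rnorm(n, 0, noise_sd)
  cq_cox1 <- base_cq_act1 - log2(strains[rows$strain]) +
    stats::rnorm(n, 0, noise_sd)
  out <- data.frame(
    strain = rep(rows$strain, 2L),
    target = rep(c("ACT1", "COX1"), each = n),
    replicate = rep(rows$replicate, 2L),
    cq = c(cq_act1, cq_cox1),
    stringsAsFactors = FALSE)
  if (any(out$cq <= 0 | out$cq >= 45)) {
    stop("generated Cq outside (0, 45); adjust base_cq_act1 or noise_sd")
  }
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Synthetic mitochondrial skeleton vertex table
#'
#' Builds a 3-D skeleton in the format emitted by network-tracing tools: one
#' row per node, nodes ordered along each line, with per-node channel
#' intensities. Each line is a straight polyline with the requested node
#' count, spacing and direction.
#'
#' @param lines list of line descriptors; each a list with `n_points`
#'   (>= 2), `spacing` (micrometres between consecutive nodes), and
#'   optionally `direction` (3-vector, default along x) and `origin`
#'   (3-vector, default the origin).
#' @param channels named list; each element is either a single number
#'   (constant intensity) or a `function(x, y, z)` evaluated per node.
#' @param compartments optional character vector, one label per line (e.g.
#'   `"P1"`, `"P2"`, `"daughter"`).
#' @param seed optional integer seed (only used if channel functions draw
#'   random numbers).
#' @return Data frame of class `vertex_table` with columns `line_id`,
#'   `point_id`, `x`, `y`, `z`, one column per channel, and `compartment`
#'   when labels are supplied.
#' @export
make_vertex_table <- function(lines, channels, compartments = NULL,
                              seed = NULL) {
  if (length(lines) < 1L) stop("at least one line is required")
  if (!is.null(compartments) && length(compartments) != length(lines)) {
    stop("one compartment label per line is required")
  }
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    stopifnot(ln$n_points >= 2L, ln$spacing > 0)
    dir <- if (is.null(ln$direction)) c(1, 0, 0) else ln$direction
    dir <- dir / sqrt(sum(dir^2))
    origin <- if (is.null(ln$origin)) c(0, 0, 0) else ln$origin
    s <- (seq_len(ln$n_points) - 1) * ln$spacing
    data.frame(line_id = i, point_id = seq_len(ln$n_points),
               x = origin[1] + s * dir[1],
               y = origin[2] + s * dir[2],
               z = origin[3] + s * dir[3])
  })
  out <- do.call(rbind, pieces)
  for (ch in names(channels)) {
    v <- channels[[ch]]
    out[[ch]] <- if (is.function(v)) v(out$x, out$y, out$z) else rep(v, nrow(out))
    if (any(out[[ch]] < 0)) stop("channel intensities must be non-negative")
  }
  if (!is.null(compartments)) out$compartment <- compartments[out$line_id]
  class(out) <- c("vertex_table", "data.frame")
  out
}

#' Read and write the tab-separated table dialect
#'
#' All synthetic tables are exchanged as tab-separated text with a one-line
#' header. `read_flow_events()` additionally enforces the acquisition cap
#' used on the cytometer: tables larger than `max_events` are subsampled with
#' a fixed seed, mirroring the per-replicate event limit of the instrument.
#'
#' @param x a data frame produced by one of the generators.
#' @param file path to read from or write to.
#' @param max_events event cap applied on read (default 10000).
#' @param seed seed for the subsampling draw.
#' @return `read_table_tsv()` and `read_flow_events()` return a data frame;
#'   `write_table_tsv()` returns `file` invisibly.
#' @export
write_table_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_table_tsv
#' @export
read_flow_events <- function(file, max_events = 10000, seed = 1L) {
  x <- read_table_tsv(file)
  if (!all(c("fsc_a", "fsc_h", "fl1") %in% names(x))) {
    stop("event table must have columns fsc_a, fsc_h, fl1")
  }
  if (nrow(x) > max_events) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), max_events), , drop = FALSE]
    rownames(x) <- NULL
  }
  class(x) <- c("flow_event_table", "data.frame")
  x
}
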