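#' Gate and classify a set of FAST replicates
#'
#' Applies the full classifier chain -- scatter gate, KDE, peak/valley
#' detection, window classification -- to each replicate event table.
#' Replicates whose fluorescence distribution is unimodal (no second peak
#' above the prominence threshold) are flagged and carry `NA` fractions;
#' they must be handled against a dark control instead.
#'
#' @param replicates named list of flow event tables (one per biological
#'   replicate).
#' @param ratio_band scatter-gate band, see [gate_scatter()].
#' @param window_frac heteroplasmic window half-width, see
#'   [classify_events()].
#' @param bandwidth KDE bandwidth, see [estimate_kde()].
#' @return Data frame with one row per replicate: counts, fractions,
#'   window bounds and a logical `unimodal` flag.
#' @export
run_fast_report <- function(replicates, ratio_band = c(0.7, 1.3),
                            window_frac = 0.10, bandwidth = "auto") {
  if (length(replicates) < 1L) stop("at least one replicate is required")
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  rows <- lapply(names(replicates), function(nm) {
    ev <- gate_scatter(replicates[[nm]], ratio_band)
    gr <- tryCatch({
      kde <- estimate_kde(ev$fl1, bandwidth)
      pv <- locate_peaks_valley(kde)
      classify_events(ev, pv, window_frac)
    }, mitofast_unimodal = function(e) NULL)
    if (is.null(gr)) {
      data.frame(replicate = nm, n_total = nrow(ev) + attr(ev, "n_removed"),
                 n_debris = attr(ev, "n_removed"), n_dark = NA_integer_,
                 n_het = NA_integer_, n_fluor = NA_integer_,
                 f_dark = NA_real_, f_het = NA_real_, f_fluor = NA_real_,
                 window_lo = NA_real_, window_hi = NA_real_,
                 unimodal = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(replicate = nm, n_total = gr$n_total,
                 n_debris = gr$n_debris, n_dark = gr$n_dark,
                 n_het = gr$n_het, n_fluor = gr$n_fluor,
                 f_dark = gr$f_dark, f_het = gr$f_het,
                 f_fluor = gr$f_fluor, window_lo = gr$window_lo,
                 window_hi = gr$window_hi, unimodal = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Compare observed dark fractions against a matched simulation
#'
#' Runs the segregation simulation under the measured founding conditions
#' (copy-number ratio and growth factor), then tests, per FAST replicate,
#' whether the simulated dark-cell fraction exceeds the observation: each
#' replicate gets a one-sided Monte-Carlo resampling p-value against the
#' simulation distribution, and replicate p-values are combined with
#' Fisher's method. A small combined p means the simulation (growth and
#' copy-number effects only) predicts more mutant-mtDNA cells than were
#' measured -- evidence for an additional intracellular mode of selection.
#'
#' @param observed observed dark-cell fractions, one per FAST replicate.
#' @param config a [sim_config()] describing the matched simulation.
#' @param B Monte-Carlo draws per replicate (default 10000).
#' @param seed optional integer seed governing simulation and resampling.
#' @param alpha significance level for the verdict (default 0.05).
#' @param alternative passed to [mc_pvalue()].
#' @param label optional cross label carried into the report.
#' @return Object of class `comparison_report`: the observed values, the
#'   simulation summary, the per-replicate p-values and Fisher combination,
#'   and a verdict (`"simulation exceeds FAST"` if `combined_p < alpha`,
#'   else `"consistent"`).
#' @export
compare_fast_to_sim <- function(observed, config, B = 10000L, seed = NULL,
                                alpha = 0.05,
                                alternative = "sim_exceeds_obs",
                                label = "cross") {
  stopifnot(length(observed) >= 1L, all(observed >= 0 & observed <= 1),
            inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sim <- run_replicates(config)
  pvals <- vapply(observed, function(obs) {
    mc_pvalue(obs, sim$mean_h, B = B, alternative = alternative)
  }, numeric(1))
  fc <- fisher_combine(pvals)
  verdict <- if (fc$combined_p < alpha) "simulation exceeds FAST" else "consistent"
  structure(list(label = label, observed = observed,
                 sim_mean = sim$mean, sim_sd = sim$sd,
                 sim_mean_h = sim$mean_h, test = fc, alpha = alpha,
                 verdict = verdict,
                 stars = significance_stars(fc$combined_p)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s: observed dark fractions %s\n", x$label,
              paste(sprintf("%.3f", x$observed), collapse = ", ")))
  cat(sprintf("  simulated mean_h = %.4f (sd %.4f, %d runs)\n",
              x$sim_mean, x$sim_sd, length(x$sim_mean_h)))
  cat(sprintf("  combined p = %.4g %s -> %s\n",
              x$test$combined_p, x$stars, x$verdict))
  invisible(x)
}

#' Serialize / restore a comparison report
#'
#' The report round-trips losslessly through its JSON form.
#'
#' @param x a `comparison_report`.
#' @param file optional path; when supplied the JSON is written there.
#' @param json a JSON string or path produced by `report_to_json()`.
#' @return `report_to_json()` returns the JSON string (invisibly when
#'   writing to a file); `report_from_json()` returns the restored
#'   `comparison_report`.
#' @export
report_to_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "comparison_report"))
  payload <- list(
    label = x$label, observed = x$observed, sim_mean = x$sim_mean,
    sim_sd = x$sim_sd, sim_mean_h = x$sim_mean_h,
    pvalues = x$test$pvalues, fisher_stat = x$test$fisher_stat,
    df = x$test$df, combined_p = x$test$combined_p, alpha = x$alpha,
    verdict = x$verdict, stars = x$stars)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  fc <- structure(list(pvalues = p$pvalues, fisher_stat = p$fisher_stat,
                       df = p$df, combined_p = p$combined_p),
                  class = "mc_test_result")
  structure(list(label = p$label, observed = p$observed,
                 sim_mean = p$sim_mean, sim_sd = p$sim_sd,
                 sim_mean_h = p$sim_mean_h, test = fc, alpha = p$alpha,
                 verdict = p$verdict, stars = p$stars),
            class = "comparison_report")
}
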