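#' Total mitochondrial network length from a skeleton vertex table
#'
#' Sums the Euclidean distances between consecutive 3-D coordinates along
#' each skeleton line (`line_id`, ordered by `point_id`), then adds these
#' per-line lengths across the network. A line with fewer than 2 nodes
#' contributes zero length (with a warning).
#'
#' @param vt vertex table with columns `line_id`, `point_id`, `x`, `y`, `z`.
#' @return Object of class `network_summary`: `total_length` (micrometres),
#'   `per_line` (named vector), `n_lines`, `n_nodes`.
#' @export
network_length <- function(vt) {
  stopifnot(is.data.frame(vt),
            all(c("line_id", "point_id", "x", "y", "z") %in% names(vt)))
  if (any(!is.finite(vt$x) | !is.finite(vt$y) | !is.finite(vt$z))) {
    stop("coordinates must be finite")
  }
  per_line <- vapply(split(vt, vt$line_id), function(d) {
    if (nrow(d) < 2L) {
      warning("line with fewer than 2 nodes contributes zero length")
      return(0)
    }
    d <- d[order(d$point_id), , drop = FALSE]
    sum(sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2))
  }, numeric(1))
  structure(list(total_length = sum(per_line), per_line = per_line,
                 n_lines = length(per_line), n_nodes = nrow(vt)),
            class = "network_summary")
}

#' Ratiometric channel summary along the network
#'
#' Two readout modes mirror the two ways ratiometric sensors are analysed:
#' `"per_node_mean"` averages the per-node numerator/denominator ratio
#' (e.g. a 400 nm / 480 nm excitation ratio computed at every network
#' point; nodes with zero denominator are excluded and counted), while
#' `"summed"` divides the channel totals (e.g. summed TMRM over summed
#' mitochondrial marker).
#'
#' @param vt vertex table carrying both channel columns.
#' @param numerator,denominator channel column names.
#' @param mode `"per_node_mean"` or `"summed"`.
#' @return Object of class `ratio_summary`: `mode`, `numerator`,
#'   `denominator`, `value`, `n_nodes` used, `n_excluded`.
#' @export
ratiometric_summary <- function(vt, numerator, denominator,
                                mode = c("per_node_mean", "summed")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(vt))
  if (!numerator %in% names(vt)) stop("missing channel: ", numerator)
  if (!denominator %in% names(vt)) stop("missing channel: ", denominator)
  num <- vt[[numerator]]
  den <- vt[[denominator]]
  if (all(den == 0)) stop("denominator channel is zero everywhere")
  if (mode == "per_node_mean") {
    ok <- den != 0
    value <- mean(num[ok] / den[ok])
    n_used <- sum(ok)
    n_excluded <- sum(!ok)
  } else {
    value <- sum(num) / sum(den)
    n_used <- length(den)
    n_excluded <- 0L
  }
  structure(list(mode = mode, numerator = numerator,
                 denominator = denominator, value = value,
                 n_nodes = n_used, n_excluded = n_excluded),
            class = "ratio_summary")
}

#' P2/P1 compartment ratio of a ratiometric metric
#'
#' Computes the chosen ratiometric summary separately on the nodes labelled
#' `"P1"` (the parental cell carrying intact mtDNA) and `"P2"` (the mating
#' partner) and returns the P2 value divided by the P1 value. Values near 1
#' indicate an equilibrated network; values below 1 indicate locally
#' reduced signal around the P2-derived mtDNA.
#'
#' @param vt vertex table with a `compartment` column containing both
#'   `"P1"` and `"P2"` labels.
#' @param numerator,denominator channel column names.
#' @param mode passed to [ratiometric_summary()].
#' @return The P2/P1 ratio (numeric).
#' @export
compartment_ratio <- function(vt, numerator, denominator,
                              mode = c("per_node_mean", "summed")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(vt))
  if (!"compartment" %in% names(vt)) stop("vertex table has no compartment labels")
  for (lab in c("P1", "P2")) {
    if (!any(vt$compartment == lab)) stop("compartment absent: ", lab)
  }
  v1 <- ratiometric_summary(vt[vt$compartment == "P1", , drop = FALSE],
                            numerator, denominator, mode)$value
  v2 <- ratiometric_summary(vt[vt$compartment == "P2", , drop = FALSE],
                            numerator, denominator, mode)$value
  if (v1 == 0) stop("P1 value is zero; ratio undefined")
  v2 / v1
}
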