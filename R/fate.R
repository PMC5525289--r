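# Membrane-fate statistics and scenario classification.
#
# From the averaged, synchronized region traces the trafficking statistics
# are computed exactly as "from X RFU to Y RFU" window readings:
#   delta_mid  = reporter gained by the mid-cell region during biogenesis,
#   delta_pm   = reporter gained by the plasma-membrane role during
#                exocytosis,
#   delta_endo = reporter gained by the cytoplasm role during exocytosis,
#   delta_ext  = reporter gained extracellularly during exocytosis,
# and the derived fractions:
#   redistribution_fraction = delta_pm / delta_mid,
#   net_synthesis_fraction  = total(valve completion)/total(baseline) - 1,
#   degraded_fraction_of_new =
#       (total(completion) - total(exo end)) / (total(completion) - baseline).
# The classifier keys on the sign pattern of these deltas to decide which
# of the four proposed SDV-membrane fates the data support.

.trace_series <- function(avg, role, channel) {
  sel <- avg$region == role & avg$channel == channel
  if (!any(sel)) return(NULL)
  d <- avg[sel, , drop = FALSE]
  d[order(d$time_min), c("time_min", "mean")]
}

.value_at <- function(series, t) {
  if (t < min(series$time_min) - 1e-9 || t > max(series$time_min) + 1e-9)
    stop("time ", t, " min outside the synchronized axis")
  series$mean[which.min(abs(series$time_min - t))]
}

#' Trace difference over a time window
#'
#' Value at the frame nearest `t_end` minus value at the frame nearest
#' `t_start` -- the programmatic form of reading "from X RFU to Y RFU" off
#' a trace.
#'
#' @param avg An `averaged_traces` object.
#' @param role Region role (`"mid"`, `"pm"`, `"cyto"`, `"ext"`).
#' @param t_start,t_end Window bounds in synchronized minutes.
#' @param channel Channel name.
#' @return The RFU difference.
#' @export
window_delta <- function(avg, role, t_start, t_end, channel = "GFP") {
  s <- .trace_series(avg, role, channel)
  if (is.null(s)) stop("no trace for role '", role, "'")
  .value_at(s, t_end) - .value_at(s, t_start)
}

#' Fraction of SDV-accumulated reporter redistributed to the plasma membrane
#'
#' @param delta_pm Reporter gained by the plasma-membrane role during
#'   exocytosis (RFU).
#' @param delta_mid Reporter accumulated in the mid-cell region during
#'   biogenesis (RFU); must be positive.
#' @return `delta_pm / delta_mid`.
#' @examples
#' redistribution_fraction(0.42 - 0.20, 1.13 - 0.27)  # ~0.256
#' @export
redistribution_fraction <- function(delta_pm, delta_mid) {
  if (!is.finite(delta_mid) || delta_mid <= 0)
    stop("'delta_mid' must be positive")
  delta_pm / delta_mid
}

#' Net synthesis over biogenesis as a fraction of the baseline total
#'
#' @param total_completion Whole-cell reporter total at valve completion.
#' @param baseline_total Whole-cell total at the pre-biogenesis baseline;
#'   must be positive.
#' @return `total_completion / baseline_total - 1`.
#' @examples
#' net_synthesis_fraction(1.13 + 0.20 + 0.16, 1.0)  # ~0.49
#' @export
net_synthesis_fraction <- function(total_completion, baseline_total) {
  if (!is.finite(baseline_total) || baseline_total <= 0)
    stop("'baseline_total' must be positive")
  total_completion / baseline_total - 1
}

#' Fraction of newly synthesized reporter degraded during exocytosis
#'
#' @param total_completion Whole-cell total at valve completion.
#' @param total_exo_end Whole-cell total at the end of exocytosis.
#' @param baseline_total Whole-cell total at the pre-biogenesis baseline.
#'   `total_completion` must exceed it.
#' @return `(total_completion - total_exo_end) / (total_completion - baseline_total)`.
#' @export
degraded_fraction_of_new <- function(total_completion, total_exo_end,
                                     baseline_total) {
  denom <- total_completion - baseline_total
  if (!is.finite(denom) || denom <= 0)
    stop("total at completion must exceed the baseline total")
  (total_completion - total_exo_end) / denom
}

#' Classify the SDV-membrane fate scenario from trace deltas
#'
#' Decision rules, evaluated against per-trace noise thresholds
#' `eps` (typically 3x the pre-event SD of each trace):
#' \itemize{
#'   \item S1 (vesicle secretion) if the extracellular gain exceeds its
#'     threshold;
#'   \item S3 (whole-membrane coat) if the mid-cell reporter retains at
#'     least `retention_threshold` of its peak after the exocytosis
#'     window;
#'   \item S4 (fusion + endocytic retrieval) if both the plasma-membrane
#'     and cytoplasm gains exceed their thresholds;
#'   \item S2 (distal coat) if the plasma-membrane gain exceeds its
#'     threshold, the cytoplasm gain does not, and a residual mid-cell
#'     signal persists;
#'   \item otherwise inconclusive.
#' }
#' Precedence on multiple fires: S1 > S3 > S4 > S2 (the extracellular and
#' full-retention signatures are the most specific). All fired flags are
#' reported.
#'
#' @param delta_pm,delta_endo,delta_ext Exocytosis-window gains (RFU).
#' @param retention Mid-cell reporter after the window as a fraction of
#'   its peak.
#' @param residual_persists Logical: does a residual mid-cell signal
#'   remain above baseline after the window?
#' @param eps Named thresholds `c(pm = , endo = , ext = )`.
#' @param retention_threshold Retention fraction counting as "all retained"
#'   (default 0.85).
#' @return List with `scenario` and `evidence` (named logical flags).
#' @export
classify_scenario <- function(delta_pm, delta_endo, delta_ext, retention,
                              residual_persists,
                              eps = c(pm = 0.01, endo = 0.01, ext = 0.01),
                              retention_threshold = 0.85) {
  fired <- c(
    S1 = isTRUE(delta_ext > eps[["ext"]]),
    S3 = isTRUE(retention >= retention_threshold),
    S4 = isTRUE(delta_pm > eps[["pm"]] && delta_endo > eps[["endo"]]),
    S2 = isTRUE(delta_pm > eps[["pm"]] && delta_endo <= eps[["endo"]] &&
                  residual_persists))
  scenario <- if (any(fired)) names(fired)[which(fired)[1L]] else "inconclusive"
  list(scenario = scenario, evidence = fired)
}

#' Infer the SDV-membrane fate from averaged traces
#'
#' The central analysis: computes the window deltas, the derived
#' trafficking fractions and the scenario classification from averaged,
#' synchronized region traces. Windows default to the canonical anchors
#' (biogenesis -87.5 to 0 min, exocytosis 0 to +10.5 min).
#'
#' @param avg An `averaged_traces` object with roles mid, pm, cyto and ext.
#' @param windows List with `biogenesis = c(start, end)` and
#'   `exocytosis = c(start, end)` in synchronized minutes.
#' @param channel Reporter channel name.
#' @param eps_mult Noise-threshold multiplier: `eps = eps_mult * SD` of
#'   each trace before biogenesis onset.
#' @param eps_min Threshold floor as a fraction of the mid-trace peak.
#'   Region sums are so well averaged that the pre-event SD can fall below
#'   the few-percent optical spillover between adjacent regions; a change
#'   smaller than `eps_min * max(mid trace)` is never counted as evidence.
#'   Expressing the floor relative to the signal keeps the classifier
#'   scale-invariant. Default 0.025.
#' @param retention_threshold See [classify_scenario()].
#' @return An object of class `sdv_fate`; see [coef.sdv_fate()],
#'   [summary.sdv_fate()], [plot.sdv_fate()].
#' @export
sdv_fate <- function(avg,
                     windows = list(biogenesis = c(-87.5, 0),
                                    exocytosis = c(0, 10.5)),
                     channel = "GFP", eps_mult = 3, eps_min = 0.025,
                     retention_threshold = 0.85) {
  stopifnot(inherits(avg, "averaged_traces"))
  roles <- c("mid", "pm", "cyto", "ext")
  series <- lapply(roles, .trace_series, avg = avg, channel = channel)
  names(series) <- roles
  missing <- roles[vapply(series, is.null, logical(1L))]
  if (length(missing))
    stop("missing region roles: ", paste(missing, collapse = ", "))
  bio <- windows$biogenesis; exo <- windows$exocytosis

  # noise thresholds from the quiet pre-biogenesis stretch of each trace
  eps <- vapply(series, function(s) {
    pre <- s$mean[s$time_min < bio[1L]]
    if (length(pre) >= 2L) eps_mult * stats::sd(pre) else 0
  }, numeric(1L))
  eps <- pmax(eps, eps_min * max(series$mid$mean))

  delta_mid <- window_delta(avg, "mid", bio[1L], bio[2L], channel)
  delta_pm <- window_delta(avg, "pm", exo[1L], exo[2L], channel)
  delta_endo <- window_delta(avg, "cyto", exo[1L], exo[2L], channel)
  delta_ext <- window_delta(avg, "ext", exo[1L], exo[2L], channel)

  mid_s <- series$mid
  mid_peak <- max(mid_s$mean)
  mid_after <- .value_at(mid_s, exo[2L])
  mid_baseline <- .value_at(mid_s, bio[1L])
  retention <- if (mid_peak > 0) mid_after / mid_peak else 0
  residual_persists <- mid_after > mid_baseline + eps[["mid"]]

  total <- function(t) sum(vapply(series, .value_at, numeric(1L), t = t))
  total_baseline <- total(bio[1L])
  total_completion <- total(bio[2L])
  total_exo_end <- total(exo[2L])

  cls <- classify_scenario(delta_pm, delta_endo, delta_ext, retention,
                           residual_persists,
                           eps = c(pm = eps[["pm"]], endo = eps[["cyto"]],
                                   ext = eps[["ext"]]),
                           retention_threshold = retention_threshold)

  structure(list(
    delta_mid = delta_mid, delta_pm = delta_pm, delta_endo = delta_endo,
    delta_ext = delta_ext,
    redistribution_fraction = redistribution_fraction(delta_pm, delta_mid),
    net_synthesis_fraction =
      net_synthesis_fraction(total_completion, total_baseline),
    degraded_fraction_of_new =
      degraded_fraction_of_new(total_completion, total_exo_end,
                               total_baseline),
    totals = c(baseline = total_baseline, completion = total_completion,
               exo_end = total_exo_end),
    retention = retention, residual_persists = residual_persists,
    scenario = cls$scenario, evidence = cls$evidence, eps = eps,
    windows = windows, channel = channel, traces = avg),
    class = "sdv_fate")
}

#' @export
print.sdv_fate <- function(x, ...) {
  cat("SDV membrane-fate analysis\n")
  cat(sprintf("  scenario: %s  (evidence fired: %s)\n", x$scenario,
              paste(names(x$evidence)[x$evidence], collapse = " ")))
  cat(sprintf("  redistribution to PM: %.1f%% of the SDV-accumulated pool\n",
              100 * x$redistribution_fraction))
  cat(sprintf("  net synthesis during biogenesis: %+.1f%%\n",
              100 * x$net_synthesis_fraction))
  cat(sprintf("  degraded fraction of new molecules: %.2f\n",
              x$degraded_fraction_of_new))
  invisible(x)
}

#' @export
summary.sdv_fate <- function(object, ...) {
  x <- object
  cat("SDV membrane-fate analysis\n")
  cat(sprintf("  windows: biogenesis %.1f..%.1f min, exocytosis %.1f..%.1f min\n",
              x$windows$biogenesis[1L], x$windows$biogenesis[2L],
              x$windows$exocytosis[1L], x$windows$exocytosis[2L]))
  cat(sprintf("  deltas (RFU): mid %+.3f (biogenesis), pm %+.3f, cyto %+.3f, ext %+.3f (exocytosis)\n",
              x$delta_mid, x$delta_pm, x$delta_endo, x$delta_ext))
  cat(sprintf("  totals (RFU): baseline %.3f -> completion %.3f -> exo end %.3f\n",
              x$totals["baseline"], x$totals["completion"],
              x$totals["exo_end"]))
  cat(sprintf("  mid-cell retention after exocytosis: %.2f of peak%s\n",
              x$retention,
              if (x$residual_persists) " (residual persists)" else ""))
  cat(sprintf("  noise thresholds (3x pre-event SD): %s\n",
              paste(sprintf("%s %.4f", names(x$eps), x$eps), collapse = ", ")))
  print(x)
  invisible(x)
}

#' Extract the fate statistics as a named vector
#'
#' @param object An `sdv_fate`.
#' @param ... Unused.
#' @return Named numeric vector of the deltas and fractions.
#' @export
coef.sdv_fate <- function(object, ...) {
  c(delta_mid = object$delta_mid, delta_pm = object$delta_pm,
    delta_endo = object$delta_endo, delta_ext = object$delta_ext,
    redistribution_fraction = object$redistribution_fraction,
    net_synthesis_fraction = object$net_synthesis_fraction,
    degraded_fraction_of_new = object$degraded_fraction_of_new,
    retention = object$retention)
}

#' @export
plot.sdv_fate <- function(x, ...) {
  plot(x$traces, channel = x$channel, ...)
  graphics::abline(v = c(x$windows$biogenesis, x$windows$exocytosis),
                   lty = 3, col = "grey40")
  invisible(x)
}

#' Write a fate report as JSON
#'
#' @param fate An `sdv_fate` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fate_report <- function(fate, path) {
  stopifnot(inherits(fate, "sdv_fate"))
  obj <- list(
    scenario = fate$scenario,
    evidence = as.list(fate$evidence),
    deltas = list(mid = fate$delta_mid, pm = fate$delta_pm,
                  endo = fate$delta_endo, ext = fate$delta_ext),
    redistribution_fraction = fate$redistribution_fraction,
    net_synthesis_fraction = fate$net_synthesis_fraction,
    degraded_fraction_of_new = fate$degraded_fraction_of_new,
    retention = fate$retention,
    totals = as.list(fate$totals),
    eps = as.list(fate$eps),
    windows = fate$windows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
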