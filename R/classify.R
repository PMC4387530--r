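# Rule-based classification of transients into the fourteen-class taxonomy
# and tabulation of class populations across replicates.

#' Classify one transient from its signature metrics
#'
#' Decision tree over the epoch structure of the response:
#' no measurable response -> 1a; slow onset (latency above
#' `rapid_latency_s`) -> 1b / 1c / W1 by whether the trace sustains,
#' decays to a plateau, or returns to baseline; rapid initial peak ->
#' branch on the post-peak epochs: repeated spikes ending in an extended
#' plateau (2c), after a mid plateau (3c) or from baseline (3b); a single
#' discrete second peak ending in a plateau (2b / W4 by whether the trace
#' first returned to baseline) or not (3a); no further events with a dual
#' plateau (W3), a sustained terminal plateau reached directly (2a) or after
#' a return to baseline (W5 under wounding), a mid plateau that decays away
#' (W2 under wounding), or a bare return to baseline (3a family under ATP,
#' W5 under wounding). Every input yields exactly one class.
#'
#' Spiking under the wound protocol contradicts the observation that wounded
#' monolayers do not spike; the class is still returned, with a warning.
#'
#' @param metrics one-row data.frame from [computeMetrics()].
#' @param trace optional trace (recomputes `metrics` when omitted fields are
#'   missing).
#' @param protocol `"ATP"` or `"wound"`.
#' @param params a [metricParams()] list (thresholds shared with the metric
#'   extractor).
#' @param stimulusTime needed only if `metrics` must be recomputed.
#' @return list with `secondary` and `primary` class labels.
#' @export
classifyTransient <- function(metrics, trace = NULL,
                              protocol = c("ATP", "wound"),
                              params = metricParams(), stimulusTime = 60) {
  protocol <- match.arg(protocol)
  need <- c("peak_height", "has_peak", "has_plateau", "is_spiking",
            "onset_latency_s", "plateau_height", "n_spikes",
            "dipped_to_baseline", "mid_plateau", "terminal_plateau",
            "dual_plateau", "baseline")
  if (!all(need %in% names(metrics))) {
    if (is.null(trace))
      stop("metrics lacks classifier fields and no trace was supplied")
    metrics <- computeMetrics(trace, stimulusTime, params)
  }
  m <- metrics[1L, ]
  atp <- protocol == "ATP"

  if (m$is_spiking && !atp)
    warning("spiking detected under the wound protocol; check thresholds")

  sec <- if (!m$has_peak && !m$has_plateau && !m$is_spiking) {
    "1a"
  } else if (!m$has_peak || m$onset_latency_s > params$rapid_latency_s) {
    # slow or delayed responders
    lateLevel <- m$plateau_height
    if (!is.na(lateLevel) && lateLevel >= params$plateau_threshold) {
      decayed <- m$has_peak && lateLevel <= 0.75 * m$peak_height
      if (decayed && !atp) "W1" else "1b"
    } else "1c"
  } else if (m$is_spiking) {
    if (m$terminal_plateau && m$has_plateau) "2c"
    else if (m$mid_plateau) "3c"
    else "3b"
  } else if (m$n_spikes == 1L) {
    # one discrete second peak
    if (m$has_plateau) {
      if (!atp && m$dipped_to_baseline) "W4" else "2b"
    } else "3a"
  } else if (m$dual_plateau && !atp) {
    "W3"
  } else if (m$has_plateau) {
    if (!atp && m$dipped_to_baseline) "W5" else "2a"
  } else if (m$mid_plateau) {
    # a plateau that later decayed away
    if (atp) "2a" else "W2"
  } else {
    # rapid peak returning to baseline with no further events
    if (atp) "3a" else "W5"
  }
  list(secondary = sec, primary = primaryClass(sec, protocol))
}

#' Extract, measure and classify every ROI of a population
#'
#' Convenience wrapper: applies [computeMetrics()] and [classifyTransient()]
#' to a list of traces (or to every ROI of an [ImageSequence-class] /
#' [ROIMap-class] pair).
#'
#' @param traces list of trace data.frames, or `NULL` if `seq`/`roimap` are
#'   given.
#' @param seq,roimap optional image sequence and ROI map to extract traces
#'   from.
#' @param protocol `"ATP"` or `"wound"`.
#' @param stimulusTime stimulus time (s); defaults to the sequence's.
#' @param params a [metricParams()] list.
#' @return data.frame with one row per cell: `id`, all metric columns,
#'   `secondary`, `primary`.
#' @export
classifyPopulation <- function(traces = NULL, seq = NULL, roimap = NULL,
                               protocol = c("ATP", "wound"),
                               stimulusTime = NULL,
                               params = metricParams()) {
  protocol <- match.arg(protocol)
  if (is.null(traces)) {
    stopifnot(is(seq, "ImageSequence"), is(roimap, "ROIMap"))
    if (is.null(stimulusTime)) stimulusTime <- seq@stimulusTime
    ids <- roimap@rois$id
    traces <- lapply(ids, function(i) extractTrace(seq, roimap, i))
  } else {
    ids <- seq_along(traces)
    if (is.null(stimulusTime)) stimulusTime <- 60
  }
  rows <- vector("list", length(traces))
  for (k in seq_along(traces)) {
    met <- computeMetrics(traces[[k]], stimulusTime, params)
    cl <- classifyTransient(met, protocol = protocol, params = params)
    met$spike_times_s <- NULL
    rows[[k]] <- cbind(data.frame(id = ids[k]), met,
                       data.frame(secondary = cl$secondary,
                                  primary = cl$primary,
                                  stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tabulate transient classes across replicates
#'
#' Builds the population table: per-replicate secondary-class counts,
#' per-replicate primary-group percentages, and the mean +- s.e.m. of each
#' primary group across replicates (s.e.m. reported as 0 with an `n = 1`
#' flag for a single replicate).
#'
#' @param labels data.frame with columns `replicate` and `secondary` (one
#'   row per cell).
#' @param protocol `"ATP"` or `"wound"`.
#' @return list of class `"ClassTable"`: `counts` (secondary x replicate
#'   matrix), `percentages` (primary x replicate), `summary` (data.frame
#'   `primary`, `mean_pct`, `sem_pct`), `n_replicates`.
#' @export
tabulateClasses <- function(labels, protocol = c("ATP", "wound")) {
  protocol <- match.arg(protocol)
  stopifnot(all(c("replicate", "secondary") %in% names(labels)),
            nrow(labels) >= 1L)
  reps <- unique(labels$replicate)
  secLevels <- transientClasses(protocol)$secondary
  extra <- setdiff(unique(labels$secondary), secLevels)
  secLevels <- c(secLevels, extra)       # tolerate out-of-protocol labels
  counts <- table(factor(labels$secondary, levels = secLevels),
                  factor(labels$replicate, levels = reps))
  counts <- unclass(counts)
  prim <- primaryClass(secLevels, protocol)
  primLevels <- unique(primaryClass(transientClasses(protocol)$secondary,
                                    protocol))
  pct <- sapply(seq_along(reps), function(j) {
    tot <- sum(counts[, j])
    vapply(primLevels, function(pl)
      if (tot == 0) 0 else 100 * sum(counts[prim == pl, j]) / tot, 0)
  })
  pct <- matrix(pct, nrow = length(primLevels),
                dimnames = list(primLevels, paste0("rep_", reps)))
  nRep <- length(reps)
  summary <- data.frame(
    primary = primLevels,
    mean_pct = rowMeans(pct),
    sem_pct = if (nRep > 1L) apply(pct, 1L, sd) / sqrt(nRep) else 0,
    stringsAsFactors = FALSE)
  out <- list(counts = counts, percentages = pct, summary = summary,
              n_replicates = nRep, protocol = protocol,
              single_replicate = nRep == 1L)
  class(out) <- "ClassTable"
  out
}

#' @export
print.ClassTable <- function(x, ...) {
  cat(sprintf("ClassTable (%s protocol, %d replicate%s)\n", x$protocol,
              x$n_replicates, if (x$n_replicates == 1) "" else "s"))
  print(x$counts)
  cat("primary-group percentages (mean +- s.e.m.):\n")
  with(x$summary, cat(sprintf("  %-14s %5.1f +- %.1f%%\n", primary,
                              mean_pct, sem_pct), sep = ""))
  invisible(x)
}

#' Plot-ready scaled feature table
#'
#' Emits min-max scaled feature pairs with a group tag, mirroring the
#' standard four-panel views: peak height vs plateau height, peak height vs
#' FWHM, plateau height vs FWHM, and each feature vs spiking rate, grouped
#' either by whether the cell subsequently spikes or by wound proximity.
#'
#' @param metrics data.frame from [classifyPopulation()] (needs
#'   `peak_height`, `plateau_height`, `fwhm_min`, `spike_rate_per_s`,
#'   `is_spiking`, and `region` when grouping by proximity).
#' @param grouping `"spiking"` or `"proximal"`.
#' @return long data.frame with columns `panel`, `x`, `y`, `group` (empty
#'   for empty input).
#' @export
featureScatter <- function(metrics, grouping = c("spiking", "proximal")) {
  grouping <- match.arg(grouping)
  empty <- data.frame(panel = character(), x = numeric(), y = numeric(),
                      group = character(), stringsAsFactors = FALSE)
  if (nrow(metrics) == 0L) return(empty)
  group <- if (grouping == "spiking") {
    ifelse(metrics$is_spiking, "spiking", "non-spiking")
  } else {
    if (!"region" %in% names(metrics))
      stop("grouping by proximity needs a 'region' column")
    metrics$region
  }
  feats <- metrics[, c("peak_height", "plateau_height", "fwhm_min",
                       "spike_rate_per_s")]
  sc <- if (nrow(feats) >= 2L)
    suppressWarnings(normalizeFeatures(feats)) else feats
  panels <- list(
    c("peak_height", "plateau_height"),
    c("peak_height", "fwhm_min"),
    c("plateau_height", "fwhm_min"),
    c("peak_height", "spike_rate_per_s"))
  do.call(rbind, lapply(panels, function(pp)
    data.frame(panel = paste(pp, collapse = "_vs_"),
               x = sc[[pp[1L]]], y = sc[[pp[2L]]], group = group,
               stringsAsFactors = FALSE)))
}
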