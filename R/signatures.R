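# Ratiometric trace extraction, slope-gated denoising, and the signature
# metrics: initial peak height A and time, FWHM B, plateau height(s) C,
# spike interval D / spiking rate.

#' Metric and classification thresholds
#'
#' @param response_threshold minimum peak height (a.u. above baseline) for a
#'   measurable initial response.
#' @param plateau_threshold minimum sustained elevation (a.u.) counted as a
#'   plateau.
#' @param plateau_min_duration_s minimum duration of a sustained plateau (s).
#' @param initial_window_s width of the initial-response window after the
#'   stimulus in which the rapid peak is sought (s).
#' @param rapid_latency_s onset latency (stimulus to half-peak on the rising
#'   edge) separating rapid from slow/delayed responders (s).
#' @param spike_prominence minimum prominence (a.u.) of a detected spike.
#' @param spike_min_separation_s minimum inter-spike separation (s).
#' @param rebase_fraction spikes must be separated by returns below
#'   baseline + this fraction of the initial peak height.
#' @param dip_fraction the trace is deemed to have returned to baseline after
#'   the initial peak if it falls below baseline + this fraction of the peak
#'   height (used to separate peak--plateau from peak--baseline--plateau).
#' @param step_threshold minimum level difference (a.u.) for a dual-plateau
#'   step.
#' @param spike_max_width_s widest stretch (s) a candidate spike may stay
#'   above half its prominence; broader elevations are plateau segments, not
#'   discrete events.
#' @param slope_threshold denoising slope gate (a.u./s): slower samples are
#'   replaced by their local mean.
#' @param denoise_window_s denoising window (s).
#' @param denoise_passes number of denoising passes applied before
#'   measurement; a second pass averages isolated samples whose noisy slope
#'   estimate leaked them through the first.
#' @return list of class `"MetricParams"`.
#' @examples
#' metricParams(response_threshold = 0.3)
#' @export
metricParams <- function(response_threshold = 0.25, plateau_threshold = 0.12,
                         plateau_min_duration_s = 300,
                         initial_window_s = 600, rapid_latency_s = 120,
                         spike_prominence = 0.18,
                         spike_min_separation_s = 120,
                         rebase_fraction = 0.25, dip_fraction = 0.15,
                         step_threshold = 0.15, spike_max_width_s = 240,
                         slope_threshold = 0.01, denoise_window_s = 5,
                         denoise_passes = 2L) {
  p <- as.list(environment())
  class(p) <- "MetricParams"
  p
}

#' Extract a ratiometric trace for one ROI
#'
#' The trace value at each frame is the mean over the ROI's pixels of the
#' ratio of the calcium-increasing over the calcium-decreasing channel, with
#' a small epsilon guarding the denominator.
#'
#' @param seq an [ImageSequence-class].
#' @param roimap an [ROIMap-class] aligned with the sequence.
#' @param roi_id ROI id to extract.
#' @param eps denominator floor (a.u.); keeps background-dominated edge
#'   pixels from exploding the ratio when noise takes the dim channel to
#'   zero.
#' @return trace `data.frame(time_s, value)`.
#' @export
extractTrace <- function(seq, roimap, roi_id, eps = 0.02) {
  stopifnot(is(seq, "ImageSequence"), is(roimap, "ROIMap"))
  idx <- which(roimap@labels == roi_id)
  if (length(idx) == 0L) stop("ROI ", roi_id, " has no pixels")
  d <- dim(seq@red)
  HW <- d[1L] * d[2L]
  offs <- (seq_len(d[3L]) - 1L) * HW
  flat <- outer(idx, offs, "+")
  polarity <- seq@metadata$imaging$dye_polarity
  if (is.null(polarity)) polarity <- "green-up"
  flat <- as.vector(flat)                 # linear indices into the stack
  up <- if (polarity == "green-up") seq@green[flat] else seq@red[flat]
  dn <- if (polarity == "green-up") seq@red[flat] else seq@green[flat]
  dim(up) <- dim(dn) <- c(length(idx), d[3L])
  vals <- colMeans(up / pmax(dn, eps))
  data.frame(time_s = (seq_len(d[3L]) - 1L) * seq@frameInterval,
             value = vals)
}

#' Slope-gated trace denoising
#'
#' Samples whose local absolute slope (central difference across the window)
#' is below `slope_threshold` are replaced by the local mean over the window;
#' rapidly changing samples — peak flanks, spikes — pass through unchanged,
#' so noise is removed from quiescent stretches without blunting transients.
#'
#' @param trace `data.frame(time_s, value)`.
#' @param slope_threshold a.u. per second.
#' @param window_s averaging window (s; at least two samples).
#' @return denoised trace of the same shape.
#' @examples
#' tr <- data.frame(time_s = 0:10, value = c(rep(1, 5), 2, rep(1, 5)))
#' denoiseTrace(tr, window_s = 5)$value[6]
#' @export
denoiseTrace <- function(trace, slope_threshold = 0.01, window_s = 5) {
  v <- trace$value; t <- trace$time_s
  n <- length(v)
  dt <- median(diff(t))
  if (window_s < 2 * dt) stop("window_s must span at least 2 samples")
  w <- .oddWindow(window_s, dt)
  h <- (w - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  slope <- abs(v[hi] - v[lo]) / (t[hi] - t[lo])
  lm <- .rollMean(v, w)
  out <- ifelse(slope < slope_threshold, lm, v)
  data.frame(time_s = t, value = out)
}

# Local maxima with prominence, for spike/second-peak detection. A candidate
# is the maximum of its +-half-window neighbourhood; its prominence is its
# height over the higher of the two valleys separating it from its
# neighbouring candidates (or the segment ends).
.findSpikes <- function(t, v, from_t, prominence, min_sep_s, floor_level,
                        max_width_s = 240) {
  keep <- t >= from_t
  if (sum(keep) < 3L) return(numeric())
  tt <- t[keep]; vv <- v[keep]
  n <- length(vv)
  dt <- median(diff(tt))
  hw <- max(1L, round(min_sep_s / 2 / dt))
  cand <- integer()
  for (i in seq_len(n)) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    if (vv[i] >= max(vv[lo:hi]) && vv[i] > floor_level) cand <- c(cand, i)
  }
  if (!length(cand)) return(numeric())
  # enforce the minimum separation, keeping the higher of any close pair
  if (length(cand) > 1L) {
    keepc <- integer()
    for (i in cand[order(-vv[cand])])
      if (!length(keepc) || all(abs(tt[i] - tt[keepc]) >= min_sep_s))
        keepc <- c(keepc, i)
    cand <- sort(keepc)
  }
  ok <- logical(length(cand))
  bounds <- c(1L, cand, n)
  for (k in seq_along(cand)) {
    i <- cand[k]
    leftMin <- min(vv[bounds[k]:i])
    rightMin <- min(vv[i:bounds[k + 2L]])
    ref <- max(leftMin, rightMin)
    if (vv[i] - ref < prominence) next
    # discreteness: the elevation above half-prominence must be short-lived,
    # otherwise it is a plateau segment, not a spike
    half <- (vv[i] + ref) / 2
    jl <- i; while (jl > 1L && vv[jl - 1L] > half) jl <- jl - 1L
    jr <- i; while (jr < n && vv[jr + 1L] > half) jr <- jr + 1L
    ok[k] <- (tt[jr] - tt[jl]) <= max_width_s
  }
  tt[cand[ok]]
}

# Apex refinement: quadratic fit to the raw trace around the located peak.
# The fitted vertex estimates the apex without the positive bias of a noisy
# maximum or the blunting of a moving average; degenerate fits fall back to
# the smoothed value at the located maximum.
.apexValue <- function(t, vRaw, vSmooth, i0, half_s = 4) {
  fallback <- list(value = vSmooth[i0], offset = 0)
  sel <- which(abs(t - t[i0]) <= half_s)
  if (length(sel) < 5L) return(fallback)
  x <- t[sel] - t[i0]
  fit <- stats::lm.fit(cbind(1, x, x^2), vRaw[sel])
  cf <- fit$coefficients
  if (anyNA(cf) || !is.finite(cf[3L]) || cf[3L] >= 0) return(fallback)
  xv <- -cf[2L] / (2 * cf[3L])
  if (abs(xv) > half_s) return(fallback)
  list(value = cf[1L] + cf[2L] * xv + cf[3L] * xv^2, offset = xv)
}

# Median of v over a time window [a, b]; NA if the window holds no samples.
.winMedian <- function(t, v, a, b) {
  sel <- t >= a & t <= b
  if (!any(sel)) NA_real_ else median(v[sel])
}

#' Compute signature metrics for one trace
#'
#' After denoising, measures the features used by the transient classifier:
#' baseline (pre-stimulus mean), initial peak height and time, onset
#' latency, FWHM (time from the peak to the first fall below baseline plus
#' half the peak height; zero by definition when there is no measurable
#' peak), plateau height (median of the final third above baseline), a
#' second plateau level when a sustained downward step is detected, spike
#' times and spiking rate (reciprocal mean inter-spike interval), plus the
#' epoch flags the classifier branches on.
#'
#' The rapid initial peak is sought inside the initial-response window; if
#' nothing measurable is found there, the search widens to the whole
#' post-stimulus trace so that slow responders report their (delayed) peak.
#'
#' @param trace `data.frame(time_s, value)`.
#' @param stimulusTime stimulus time (s), within the trace.
#' @param params a [metricParams()] list.
#' @param denoise apply [denoiseTrace()] first (default `TRUE`).
#' @return one-row `data.frame` with columns `baseline`, `peak_height`,
#'   `peak_time_min`, `onset_latency_s`, `fwhm_min`, `plateau_height`,
#'   `plateau2_height`, `spike_rate_per_s`, `n_spikes`, `has_peak`,
#'   `has_plateau`, `is_spiking`, `dipped_to_baseline`, `mid_plateau`,
#'   `terminal_plateau`, `dual_plateau`, and a list-column `spike_times_s`.
#' @examples
#' tr <- data.frame(time_s = 0:499, value = 1)
#' computeMetrics(tr, stimulusTime = 50)$peak_height
#' @export
computeMetrics <- function(trace, stimulusTime, params = metricParams(),
                           denoise = TRUE) {
  stopifnot(all(c("time_s", "value") %in% names(trace)))
  t <- trace$time_s
  if (stimulusTime < t[1L] || stimulusTime > t[length(t)])
    stop("stimulusTime must lie within the trace")
  vRaw <- trace$value
  if (denoise) {
    win <- max(params$denoise_window_s, 2 * median(diff(t)))
    for (pass in seq_len(params$denoise_passes))
      trace <- denoiseTrace(trace, params$slope_threshold, win)
  }
  vDen <- trace$value
  n <- length(vDen)
  tEnd <- t[n]
  dtMed <- median(diff(t))
  # measurement copy: a short centred moving average so that crossings and
  # maxima are not driven by single-sample noise
  v <- .rollMean(vDen, .oddWindow(5, dtMed))

  zeroed <- data.frame(baseline = NA_real_, peak_height = 0,
                       peak_time_min = NA_real_, onset_latency_s = Inf,
                       fwhm_min = 0, plateau_height = 0, plateau2_height = 0,
                       spike_rate_per_s = 0, n_spikes = 0L, has_peak = FALSE,
                       has_plateau = FALSE, is_spiking = FALSE,
                       dipped_to_baseline = FALSE, mid_plateau = FALSE,
                       terminal_plateau = FALSE, dual_plateau = FALSE)
  zeroed$spike_times_s <- list(numeric())

  pre <- t < stimulusTime
  base <- if (any(pre)) mean(v[pre])
          else mean(v[seq_len(max(1L, ceiling(0.05 * n)))])

  post <- which(t >= stimulusTime)
  if (length(post) < 2L) { zeroed$baseline <- base; return(zeroed) }

  # initial peak: a sharp (5 s resolution, apex-fitted) search inside the
  # response window for the rapid peak, and a coarse (30 s smoothing) search
  # over the whole post-stimulus trace whose time scale matches delayed and
  # sub-threshold responses. The coarse estimate wins when the window holds
  # nothing measurable, the late trace clearly exceeds it, or the window
  # maximum sits on its trailing edge with the trace still rising.
  win <- post[t[post] <= stimulusTime + params$initial_window_s]
  iPk <- win[which.max(v[win])]
  apex <- .apexValue(t, vRaw, v, iPk)
  sharpHeight <- max(0, apex$value - base)
  vSlow <- .rollMean(vDen, .oddWindow(31, dtMed))
  iGlobal <- post[which.max(vSlow[post])]
  slowHeight <- max(0, vSlow[iGlobal] - base)
  stillRising <- t[iPk] >= stimulusTime + params$initial_window_s - 60 &&
    slowHeight > sharpHeight
  delayed <- sharpHeight < params$response_threshold ||
    ((slowHeight - sharpHeight > max(0.05, 0.1 * sharpHeight) || stillRising)
     && slowHeight >= params$response_threshold)
  if (delayed) {
    iPk <- iGlobal
    peakHeight <- slowHeight
    nb <- which(abs(t - t[iPk]) <= 30)
    tPk <- t[nb[which.max(vRaw[nb])]]
  } else {
    peakHeight <- sharpHeight
    # report the raw-sample apex time near the located maximum; the raw
    # argmax is exact for clean data where smoothing can shift the top of
    # an asymmetric peak by a sample
    nb <- which(abs(t - t[iPk]) <= 5)
    tPk <- t[nb[which.max(vRaw[nb])]]
  }
  hasPeak <- peakHeight >= params$response_threshold
  halfLevel <- base + peakHeight / 2

  latency <- Inf
  if (hasPeak) {
    iOn <- post[post <= iPk & v[post] >= halfLevel]
    if (length(iOn)) latency <- t[iOn[1L]] - stimulusTime
  }

  # the half-maximum crossing must persist (15 s) so that a single noise
  # excursion does not end the FWHM early
  fwhm_s <- 0
  iCross <- NA_integer_
  if (hasPeak) {
    after <- which(t > tPk & v < halfLevel)
    for (i in after) {
      if (.winMedian(t, v, t[i], min(t[i] + 15, tEnd)) < halfLevel) {
        iCross <- i
        break
      }
    }
    fwhm_s <- if (!is.na(iCross)) t[iCross] - tPk else tEnd - tPk
  }

  # return towards baseline after the peak? (persistence as above)
  dipLevel <- base + params$dip_fraction * peakHeight
  dipped <- FALSE
  if (hasPeak) {
    for (i in which(t > tPk & v <= dipLevel)) {
      if (.winMedian(t, v, t[i], min(t[i] + 15, tEnd)) <= dipLevel) {
        dipped <- TRUE
        break
      }
    }
  }

  # spikes after the initial response has passed: search from the first fall
  # of the falling edge below 75% of the peak (a sustained plateau that high
  # means no discrete post-peak events can be resolved)
  searchFrom <- if (hasPeak) {
    iFall <- which(t > tPk & v < base + 0.75 * peakHeight)
    if (length(iFall)) t[iFall[1L]] + 30 else Inf
  } else stimulusTime + params$initial_window_s
  spikes <- .findSpikes(t, v, searchFrom, params$spike_prominence,
                        params$spike_min_separation_s,
                        floor_level = base + params$spike_prominence / 2,
                        max_width_s = params$spike_max_width_s)
  nSpikes <- length(spikes)
  isSpiking <- nSpikes >= 2L
  spikeRate <- if (isSpiking) 1 / mean(diff(spikes)) else 0

  # plateau levels; spike neighbourhoods are masked so that a spiking tail
  # does not read as a small sustained elevation
  spikeFree <- rep(TRUE, n)
  for (st in spikes)
    spikeFree[abs(t - st) <= params$spike_max_width_s / 2] <- FALSE
  medFree <- function(a, b) {
    sel <- t >= a & t <= b & spikeFree
    if (!any(sel)) .winMedian(t, v, a, b) else median(v[sel])
  }
  lateFrom <- t[1L] + 2 / 3 * (tEnd - t[1L])
  plateau <- medFree(lateFrom, tEnd) - base
  termFrom <- if (nSpikes > 0L) max(spikes) + 90 else tEnd -
    params$plateau_min_duration_s
  terminal <- FALSE
  if (tEnd - termFrom >= params$plateau_min_duration_s) {
    tm <- medFree(termFrom, tEnd)
    terminal <- !is.na(tm) && tm - base >= params$plateau_threshold
  }

  # level of the early post-peak epoch (before any spiking and before the
  # terminal stretch); capped at 10 min so a plateau that later decays away
  # is still seen as one
  midPlateau <- FALSE; midLevel <- NA_real_
  if (hasPeak) {
    midA <- tPk + fwhm_s + 30
    midB <- min(midA + 600,
                if (nSpikes > 0L) min(spikes) - 60 else Inf,
                lateFrom)
    if (midB - midA >= params$plateau_min_duration_s) {
      midLevel <- .winMedian(t, v, midA, midB) - base
      midPlateau <- !is.na(midLevel) && midLevel >= params$plateau_threshold
    }
  }

  # dual plateau: a sustained downward step between two post-peak levels,
  # both above the plateau threshold
  dual <- FALSE; plateau2 <- 0
  if (hasPeak && !isSpiking && !is.na(iCross)) {
    # start after the peak's decay has settled, so a slow decay through
    # intermediate levels is not mistaken for a step
    segA <- tPk + 2 * fwhm_s + 60
    minSeg <- params$plateau_min_duration_s
    if (tEnd - segA >= 2 * minSeg) {
      cuts <- seq(segA + minSeg, tEnd - minSeg, by = 60)
      stable <- function(a, b) {
        mid <- (a + b) / 2
        abs(.winMedian(t, v, a, mid) - .winMedian(t, v, mid, b)) <=
          params$step_threshold / 2
      }
      if (length(cuts)) {
        m1 <- vapply(cuts, function(cu) .winMedian(t, v, segA, cu), 0)
        m2 <- vapply(cuts, function(cu) .winMedian(t, v, cu, tEnd), 0)
        step <- m1 - m2
        # a qualifying cut leaves two flat segments, both above the plateau
        # threshold, separated by a sufficient downward step
        qual <- which(step >= params$step_threshold &
                      m2 - base >= params$plateau_threshold &
                      m1 - base >= params$plateau_threshold)
        qual <- qual[vapply(qual, function(k)
          stable(segA, cuts[k]) && stable(cuts[k] + 60, tEnd), NA)]
        if (length(qual)) {
          k <- qual[which.max(step[qual])]
          dual <- TRUE
          plateau2 <- m2[k] - base       # terminal level
          plateau <- m1[k] - base        # first plateau is the headline C
        }
      }
    }
  }

  hasPlateau <- (plateau >= params$plateau_threshold && terminal) || dual
  if (hasPeak && is.finite(plateau)) plateau <- min(plateau, peakHeight)

  out <- data.frame(baseline = base, peak_height = peakHeight,
                    peak_time_min = (tPk - stimulusTime) / 60,
                    onset_latency_s = latency, fwhm_min = fwhm_s / 60,
                    plateau_height = plateau, plateau2_height = plateau2,
                    spike_rate_per_s = spikeRate, n_spikes = nSpikes,
                    has_peak = hasPeak, has_plateau = hasPlateau,
                    is_spiking = isSpiking, dipped_to_baseline = dipped,
                    mid_plateau = midPlateau, terminal_plateau = terminal,
                    dual_plateau = dual)
  out$spike_times_s <- list(spikes)
  if (!hasPeak) { out$fwhm_min <- 0 }
  out
}

#' Min-max scale feature columns to [0, 1]
#'
#' Used for scatter/cluster displays only; classification always works on
#' unscaled values. Constant features map to all zeros and are flagged.
#'
#' @param x data.frame of numeric features (>= 2 rows).
#' @return data.frame of the same shape scaled to [0, 1], with attributes
#'   `scale_min`, `scale_range` (for inversion) and `degenerate` (names of
#'   constant columns).
#' @examples
#' normalizeFeatures(data.frame(a = c(2, 4, 6)))
#' @export
normalizeFeatures <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) >= 2L)
  mins <- vapply(x, min, 0, na.rm = TRUE)
  rngs <- vapply(x, function(col) diff(range(col, na.rm = TRUE)), 0)
  degenerate <- names(x)[rngs == 0]
  if (length(degenerate))
    warning("constant feature(s) scaled to zero: ",
            paste(degenerate, collapse = ", "))
  out <- as.data.frame(Map(function(col, m, r)
    if (r == 0) rep(0, length(col)) else (col - m) / r, x, mins, rngs))
  names(out) <- names(x)
  attr(out, "scale_min") <- mins
  attr(out, "scale_range") <- rngs
  attr(out, "degenerate") <- degenerate
  out
}
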