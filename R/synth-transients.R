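# Synthetic calcium transients and populations.

#' Generate one synthetic calcium transient
#'
#' Evaluates the noiseless class waveform defined by `params` on a time grid
#' and adds Gaussian trace noise. Values are clipped at zero (fluorescence
#' ratios cannot be negative).
#'
#' @param params a [transientParams()] object.
#' @param times strictly increasing numeric vector of sample times in seconds
#'   from the start of the recording (at least two samples).
#' @param seed optional integer seed for the trace noise.
#' @param stimulusTime stimulus (agonist arrival / wounding) time in seconds.
#' @return A trace: `data.frame(time_s, value)`.
#' @examples
#' p <- transientParams("2a", peak_amplitude = 1, plateau_level = 0.79)
#' tr <- makeTransient(p, times = 0:2159, seed = 1)
#' range(tr$value)
#' @export
makeTransient <- function(params, times, seed = NULL, stimulusTime = 60) {
  stopifnot(inherits(params, "TransientParams"))
  if (length(times) < 2L) stop("time grid must contain at least 2 samples")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  v <- .evalTransient(params, times, stimulusTime)
  if (params$noise_sd > 0)
    v <- .withSeed(seed, v + rnorm(length(v), 0, params$noise_sd))
  data.frame(time_s = times, value = pmax(v, 0))
}

# Ground-truth signature values implied by the parameters. Peak height/time
# and spike rate come directly from the parameters; FWHM and plateau are read
# off the noiseless waveform with direct rules (first half-max down-crossing
# after the peak; median of the final third), independent of computeMetrics.
.truthMetrics <- function(params, times, stimulusTime = 60,
                          response_threshold = 0.25) {
  v <- .evalTransient(params, times, stimulusTime)
  base <- params$baseline
  A <- params$peak_amplitude
  fwhm <- 0
  if (A >= response_threshold) {
    tpk <- stimulusTime + params$peak_time_s
    after <- which(times > tpk & v < base + A / 2)
    fwhm <- if (length(after)) times[after[1L]] - tpk
            else max(times) - tpk
  }
  lastThird <- times >= times[1L] + 2 / 3 * (max(times) - times[1L])
  # exclude the neighbourhood of discrete events, matching the spike-masked
  # plateau estimator
  ev <- stimulusTime + c(.spikeTimes(params, max(times) - stimulusTime),
                         params$second_peak_time_s)
  ev <- ev[is.finite(ev)]
  clear <- lastThird
  for (e in ev) clear <- clear & abs(times - e) > 120
  if (!any(clear)) clear <- lastThird
  plateau <- median(v[clear]) - base
  nsp <- length(.spikeTimes(params, max(times) - stimulusTime))
  rate <- if (nsp >= 2L) 1 / params$spike_interval_s else 0
  data.frame(true_peak = A,
             true_peak_time_s = params$peak_time_s,
             true_fwhm_s = fwhm,
             true_plateau = plateau,
             true_spike_rate = rate,
             true_has_peak = A >= response_threshold)
}

#' Generate a synthetic population of transients
#'
#' Draws secondary classes from a mixture, then per-cell parameters from the
#' per-class priors, and synthesises one noisy trace per cell.
#'
#' @param mixture named numeric vector of class probabilities (names are
#'   secondary class labels); must be nonnegative and sum to 1.
#' @param n number of cells (>= 1).
#' @param protocol `"ATP"` or `"wound"`.
#' @param priors optional named list of functions, one per class label; each
#'   is called as `fn()` and must return a [transientParams()] object.
#'   Classes without an entry use the built-in samplers
#'   (see [sampleClassParams()]).
#' @param seed integer seed; the whole population is reproducible given the
#'   seed.
#' @param duration_s recording length (s); defaults to 35 min post-stimulus
#'   for ATP and 45 min for wound.
#' @param dt_s sample interval (s).
#' @param stimulusTime stimulus time (s).
#' @param noise_sd trace noise passed to the built-in samplers.
#' @return list with `traces` (list of trace data.frames), `truth`
#'   (data.frame: `id`, `secondary`, `primary`, generating signature values,
#'   and a `params` list-column).
#' @examples
#' pop <- makePopulation(c("1a" = 1), n = 3, seed = 1)
#' length(pop$traces)
#' @export
makePopulation <- function(mixture, n, protocol = c("ATP", "wound"),
                           priors = NULL, seed = NULL, duration_s = NULL,
                           dt_s = 1, stimulusTime = 60, noise_sd = 0.05) {
  protocol <- match.arg(protocol)
  if (length(mixture) == 0L) stop("mixture must not be empty")
  if (is.null(names(mixture)) || !all(names(mixture) %in% .ALL_SECONDARY))
    stop("mixture must be named with secondary class labels")
  if (any(mixture < 0)) stop("mixture probabilities must be nonnegative")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture probabilities must sum to 1")
  if (n < 1L) stop("n must be >= 1")
  if (is.null(duration_s))
    duration_s <- stimulusTime + if (protocol == "ATP") 2100 else 2700
  times <- seq(0, duration_s, by = dt_s)

  .withSeed(seed, {
    classes <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    traces <- vector("list", n)
    paramsList <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      p <- if (!is.null(priors[[cl]])) priors[[cl]]()
           else sampleClassParams(cl, protocol, noise_sd = noise_sd)
      paramsList[[i]] <- p
      traces[[i]] <- makeTransient(p, times, stimulusTime = stimulusTime)
      truth[[i]] <- .truthMetrics(p, times, stimulusTime)
    }
    truth <- do.call(rbind, truth)
    truth <- cbind(data.frame(id = seq_len(n), secondary = classes,
                              primary = primaryClass(classes, protocol),
                              stringsAsFactors = FALSE),
                   truth)
    truth$params <- paramsList
    list(traces = traces, truth = truth, times = times,
         stimulusTime = stimulusTime, protocol = protocol)
  })
}
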