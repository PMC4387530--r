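# Built-in per-class parameter priors.
#
# Amplitude and timing moments for the agonist protocol follow the published
# per-class population summaries (class-2 peak 1.04, plateau 0.79, FWHM
# 3.92 min; class-3 peak 0.98, spike rate ~1.9e-3 s^-1; class-1 peak 0.11);
# wound-protocol amplitudes come from the proximal/distal moment table (peak
# 1.301/0.4895 vs 0.5484/0.5854, etc.). Nonnegative quantities are drawn
# lognormally by moments; shape-timing values are clipped so that each
# class's defining predicate holds with a margin (see the methods vignette).

.clip <- function(x, lo, hi) pmin(pmax(x, lo), max(hi, lo))

#' Wound-proximity response model
#'
#' Generative moments for cells proximal (< 100 um) and distal (>= 100 um)
#' to the wound edge: class mixtures plus lognormal moments for peak height,
#' plateau height, FWHM and peak time.
#'
#' @param threshold_um proximal/distal boundary (um).
#' @return list with elements `proximal`, `distal` (each holding `mixture`,
#'   `peak`, `plateau`, `fwhm_s`, `peak_time_s` as `c(mean, sd)` vectors) and
#'   `threshold_um`.
#' @examples
#' woundResponseModel()$proximal$peak
#' @export
woundResponseModel <- function(threshold_um = 100) {
  list(
    proximal = list(
      mixture = woundClassMixture("proximal"),
      peak = c(mean = 1.301, sd = 0.4895),
      plateau = c(mean = 0.3156, sd = 0.2919),
      fwhm_s = c(mean = 3.176 * 60, sd = 4.657 * 60),
      peak_time_s = c(mean = 1.033 * 60, sd = 3.275 * 60)),
    distal = list(
      mixture = woundClassMixture("distal"),
      peak = c(mean = 0.5484, sd = 0.5854),
      plateau = c(mean = 0.1648, sd = 0.08274),
      fwhm_s = c(mean = 0.7623 * 60, sd = 0.9670 * 60),
      peak_time_s = c(mean = 0.5132 * 60, sd = 0.8725 * 60)),
    threshold_um = threshold_um)
}

#' Draw transient parameters for one cell of a given class
#'
#' The built-in priors behind [makePopulation()] and the layout generators.
#' Draws are made from the current RNG stream (seed management is the
#' caller's job).
#'
#' @param class_label secondary class label.
#' @param protocol `"ATP"` or `"wound"`.
#' @param region for the wound protocol, `"proximal"` or `"distal"`; ignored
#'   for ATP.
#' @param model a [woundResponseModel()]; used only for the wound protocol.
#' @param noise_sd trace noise s.d. (a.u.).
#' @return A [transientParams()] object.
#' @examples
#' withr::with_seed(1, sampleClassParams("2a"))
#' @export
sampleClassParams <- function(class_label, protocol = c("ATP", "wound"),
                              region = c("distal", "proximal"),
                              model = woundResponseModel(),
                              noise_sd = 0.05) {
  protocol <- match.arg(protocol)
  region <- match.arg(region)
  base <- .rnormT(1, 1, 0.03, 0.85, 1.15)
  if (protocol == "ATP")
    .sampleATP(class_label, base, noise_sd)
  else
    .sampleWound(class_label, base, noise_sd, model[[region]])
}

.sampleATP <- function(cl, base, noise_sd) {
  tp <- function(...) transientParams(cl, "ATP", baseline = base,
                                      noise_sd = noise_sd, ...)
  switch(cl,
    "1a" = tp(),
    "1b" = tp(peak_amplitude = .clip(.rlnormM(1, 0.35, 0.12), 0.3, 1),
              peak_time_s = runif(1, 1500, 2000),
              rise_tau_s = runif(1, 260, 380), decay_tau_s = 2500),
    "1c" = tp(peak_amplitude = .clip(.rlnormM(1, 0.40, 0.15), 0.32, 1.2),
              peak_time_s = runif(1, 650, 1100),
              rise_tau_s = runif(1, 160, 260),
              decay_tau_s = .rlnormM(1, 180, 50)),
    "2a" = {
      A <- .rlnormM(1, 1.04, 0.19)
      fw <- .clip(.rlnormM(1, 235, 110), 60, 900)
      tp(peak_amplitude = A,
         peak_time_s = .rnormT(1, 68, 10, 40, 120),
         rise_tau_s = runif(1, 10, 18), decay_tau_s = fw / log(2),
         plateau_level = .clip(.rlnormM(1, 0.79, 0.19), 0.2, 0.9 * A))
    },
    "2b" = {
      A <- .rlnormM(1, 1.05, 0.20)
      C <- .clip(.rlnormM(1, 0.60, 0.15), 0.25, 0.7 * A)
      fw <- .clip(.rlnormM(1, 220, 90), 60, 700)
      tp(peak_amplitude = A,
         peak_time_s = .rnormT(1, 68, 10, 40, 120),
         rise_tau_s = runif(1, 10, 18), decay_tau_s = fw / log(2),
         plateau_level = C,
         spike_interval_s = runif(1, 600, 1100),
         spike_amplitude = .clip(.rlnormM(1, 0.32, 0.08), 0.26,
                                 0.85 * (A - C)))
    },
    "2c" = {
      A <- .rlnormM(1, 1.00, 0.20)
      onset <- runif(1, 1500, 1700)
      pk <- .rnormT(1, 68, 10, 40, 120)
      tp(peak_amplitude = A, peak_time_s = pk,
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = .clip(.rlnormM(1, 150, 50), 60, 400) / log(2),
         plateau_level = .clip(.rlnormM(1, 0.50, 0.12), 0.2, 0.8 * A),
         plateau_onset_s = onset,
         spike_start_s = pk + runif(1, 250, 350),
         spike_end_s = onset - 120,
         spike_interval_s = .clip(.rlnormM(1, 280, 70), 150, 450),
         spike_amplitude = .clip(.rlnormM(1, 0.45, 0.10), 0.28, 0.8 * A))
    },
    "3a" = {
      A <- .rlnormM(1, 0.98, 0.20)
      tp(peak_amplitude = A,
         peak_time_s = .rnormT(1, 60, 10, 40, 120),
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = .clip(.rlnormM(1, 120, 35), 50, 300) / log(2),
         spike_interval_s = runif(1, 500, 900),
         spike_amplitude = .clip(.rlnormM(1, 0.55, 0.12), 0.3, 0.9 * A))
    },
    "3b" = {
      A <- .rlnormM(1, 0.98, 0.20)
      pk <- .rnormT(1, 60, 10, 40, 120)
      tp(peak_amplitude = A, peak_time_s = pk,
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = .clip(.rlnormM(1, 120, 35), 50, 300) / log(2),
         spike_start_s = pk + runif(1, 250, 400),
         spike_interval_s = .clip(.rlnormM(1, 525, 150), 250, 900),
         spike_amplitude = .clip(.rlnormM(1, 0.50, 0.12), 0.28, 0.8 * A))
    },
    "3c" = {
      A <- .rlnormM(1, 0.98, 0.20)
      C <- .clip(.rlnormM(1, 0.40, 0.10), 0.18, 0.42 * A)
      fw <- .clip(.rlnormM(1, 140, 40), 60, 350)
      pend <- runif(1, 900, 1300)
      tp(peak_amplitude = A,
         peak_time_s = .rnormT(1, 65, 10, 40, 120),
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = fw / log((A - C) / (A / 2 - C)),
         plateau_level = C, plateau_end_s = pend,
         spike_start_s = pend + 150,
         spike_interval_s = .clip(.rlnormM(1, 420, 120), 200, 800),
         spike_amplitude = .clip(.rlnormM(1, 0.50, 0.12), 0.3, 0.8 * A))
    },
    stop("unknown ATP class: ", cl))
}

.sampleWound <- function(cl, base, noise_sd, m) {
  tp <- function(...) transientParams(cl, "wound", baseline = base,
                                      noise_sd = noise_sd, ...)
  drawA <- function(lo = 0.3) .clip(.rlnormM(1, m$peak[1], m$peak[2]), lo, 4)
  drawFW <- function(lo = 30, hi = 600)
    .clip(.rlnormM(1, m$fwhm_s[1], m$fwhm_s[2]), lo, hi)
  # rapid-onset classes: the peak must fall inside the rapid-latency window
  drawPT <- function() .rnormT(1, m$peak_time_s[1], m$peak_time_s[2], 25, 130)
  drawC <- function(lo, hi)
    .clip(.rlnormM(1, m$plateau[1], m$plateau[2]), lo, hi)

  switch(cl,
    "1a" = tp(),
    "1b" = tp(peak_amplitude = .clip(.rlnormM(1, 0.35, 0.12), 0.3, 1),
              peak_time_s = runif(1, 1500, 2400),
              rise_tau_s = runif(1, 260, 380), decay_tau_s = 2500),
    "1c" = tp(peak_amplitude = .clip(.rlnormM(1, 0.40, 0.15), 0.32, 1.2),
              peak_time_s = runif(1, 650, 1100),
              rise_tau_s = runif(1, 160, 260),
              decay_tau_s = .rlnormM(1, 180, 50)),
    "W1" = {
      A <- .clip(.rlnormM(1, m$peak[1], m$peak[2]), 0.35, 3)
      pk <- runif(1, 700, 1200)
      C <- drawC(max(0.2, 0.3 * A), 0.6 * A)
      tp(peak_amplitude = A, peak_time_s = pk,
         rise_tau_s = pk * runif(1, 0.18, 0.28),
         decay_tau_s = .rlnormM(1, 250, 80),
         plateau_level = C)
    },
    "2a" = {
      A <- drawA()
      C <- .clip(.rlnormM(1, m$plateau[1], m$plateau[2]),
                 max(0.15, 0.22 * A), 0.45 * A)
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18), decay_tau_s = drawFW() / log(2),
         plateau_level = C)
    },
    "2b" = {
      A <- drawA()
      C <- .clip(.rlnormM(1, m$plateau[1], m$plateau[2]),
                 max(0.18, 0.25 * A), 0.45 * A)
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18), decay_tau_s = drawFW() / log(2),
         plateau_level = C,
         spike_interval_s = runif(1, 600, 1100),
         spike_amplitude = .clip(.rlnormM(1, 0.32, 0.08), 0.26,
                                 0.85 * (A - C)))
    },
    "W2" = {
      A <- drawA(lo = 0.7)
      C <- drawC(max(0.3, 0.25 * A), 0.45 * A)
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18), decay_tau_s = drawFW() / log(2),
         plateau_level = C, plateau_end_s = runif(1, 900, 1400))
    },
    "W3" = {
      A <- drawA(lo = 1.0)
      C <- drawC(max(0.45, 0.17 * A + 0.2), 0.45 * A)
      C2 <- .clip(0.45 * C, max(0.2, 0.17 * A), C - 0.2)
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = drawFW(hi = 250) / log(2),
         plateau_level = C, plateau2_level = C2,
         plateau_end_s = runif(1, 1100, 1500))
    },
    "W4" = {
      A <- drawA()
      off <- runif(1, 500, 900)
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = drawFW(lo = 30, hi = 300) / log(2),
         plateau_level = drawC(max(0.2, 0.25 * A), 0.6 * A),
         spike_interval_s = off,
         spike_amplitude = .clip(.rlnormM(1, 0.50, 0.15), 0.3, 0.9 * A))
    },
    "W5" = {
      A <- drawA()
      tp(peak_amplitude = A, peak_time_s = drawPT(),
         rise_tau_s = runif(1, 10, 18),
         decay_tau_s = drawFW(lo = 30, hi = 300) / log(2),
         plateau_level = drawC(max(0.2, 0.25 * A), 0.65 * A),
         plateau_onset_s = runif(1, 700, 1100))
    },
    stop("class ", cl, " is not generated under the wound protocol"))
}
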