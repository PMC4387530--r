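# Per-cell transient parameterisation.
#
# A transient is composed of a baseline, an initial peak (exponential rise
# to the peak time, exponential decay after it), a plateau that ramps in
# exponentially (and may end, either decaying back to baseline or relaxing
# onto a second, lower level), one optional discrete second peak, and a
# train of raised-cosine spikes. The peak and plateau terms combine through
# their pointwise maximum: with the plateau onset at the peak time the decay
# lands directly on the plateau, while a later onset produces a partial
# return towards baseline before the plateau establishes — and in either
# case the post-dip approach to the plateau is monotone, so the transition
# never masquerades as a discrete calcium spike. Discrete events add on top.

.PARAM_FIELDS <- c("class_label", "protocol", "baseline", "peak_amplitude",
  "peak_time_s", "rise_tau_s", "decay_tau_s", "plateau_level",
  "plateau2_level", "spike_interval_s", "spike_amplitude", "noise_sd",
  "plateau_onset_s", "plateau_tau_s", "plateau_end_s", "plateau_end_tau_s",
  "spike_start_s", "spike_end_s", "second_peak_time_s", "event_width_s")

#' Parameters of one synthetic calcium transient
#'
#' Bundles the generating parameters of a single cell's transient: baseline
#' ratio, initial peak amplitude `A` and its timing, plateau level(s) `C`
#' (and the second plateau level for dual-plateau responses), the spike
#' interval `D` and amplitude, and the trace noise level. Shape-timing fields
#' left `NULL` are filled with class-appropriate defaults.
#'
#' @param class_label secondary transient class (`"1a"` ... `"3c"`,
#'   `"W1"` ... `"W5"`).
#' @param protocol `"ATP"` or `"wound"`; wound-only classes require the wound
#'   protocol.
#' @param baseline resting ratio level (a.u.).
#' @param peak_amplitude initial peak height `A` above baseline (a.u.).
#' @param peak_time_s time of the initial peak, seconds after stimulus.
#' @param rise_tau_s,decay_tau_s rise/decay time constants of the initial
#'   peak (s); `decay_tau_s = Inf` gives a sustained rise.
#' @param plateau_level plateau height `C` above baseline (a.u.).
#' @param plateau2_level second (lower) plateau height for dual-plateau
#'   responses (a.u.).
#' @param spike_interval_s inter-spike interval `D` (s); for the
#'   double-peak classes (`2b`, `3a`, `W4`) this is the offset of the second
#'   peak from the first.
#' @param spike_amplitude spike / second-peak amplitude (a.u.).
#' @param noise_sd additive Gaussian trace noise s.d. (a.u.).
#' @param plateau_onset_s,plateau_tau_s plateau onset (s after stimulus) and
#'   ramp time constant; defaults depend on the class shape.
#' @param plateau_end_s,plateau_end_tau_s end of the (first) plateau and the
#'   relaxation time constant towards baseline or the second plateau.
#' @param spike_start_s,spike_end_s span of the spike train (s after
#'   stimulus).
#' @param second_peak_time_s time of the discrete second peak.
#' @param event_width_s full width of raised-cosine spikes/second peaks (s).
#' @return A list of class `"TransientParams"`.
#' @examples
#' p <- transientParams("2a", peak_amplitude = 1, plateau_level = 0.79)
#' p$decay_tau_s
#' @export
transientParams <- function(class_label,
                            protocol = c("ATP", "wound"),
                            baseline = 1,
                            peak_amplitude = 0,
                            peak_time_s = 68,
                            rise_tau_s = 15,
                            decay_tau_s = 340,
                            plateau_level = 0,
                            plateau2_level = 0,
                            spike_interval_s = 0,
                            spike_amplitude = 0,
                            noise_sd = 0,
                            plateau_onset_s = NULL,
                            plateau_tau_s = NULL,
                            plateau_end_s = NULL,
                            plateau_end_tau_s = 90,
                            spike_start_s = NULL,
                            spike_end_s = NULL,
                            second_peak_time_s = NULL,
                            event_width_s = 120) {
  protocol <- match.arg(protocol)
  if (length(class_label) != 1L || !class_label %in% .ALL_SECONDARY)
    stop("unknown class_label: ", paste(class_label, collapse = ", "))
  if (protocol == "ATP" && class_label %in% .WOUND_EXTRA)
    stop("class ", class_label, " only occurs under the wound protocol")
  for (nm in c("baseline", "peak_amplitude", "plateau_level",
               "plateau2_level", "spike_amplitude", "noise_sd"))
    .assertScalarNum(get(nm), nm, lo = 0)
  .assertScalarNum(peak_time_s, "peak_time_s", lo = 0)
  .assertScalarNum(rise_tau_s, "rise_tau_s", lo = 0, strict = TRUE)
  if (!(is.numeric(decay_tau_s) && length(decay_tau_s) == 1L &&
        decay_tau_s > 0))
    stop("'decay_tau_s' must be a single positive number (Inf allowed)")
  spiking <- class_label %in% .SPIKING_CLASSES
  secondPeak <- class_label %in% c("2b", "3a", "W4")
  if (spiking && spike_interval_s <= 0)
    stop("spike_interval_s must be > 0 for spiking class ", class_label)
  if (secondPeak && spike_interval_s <= 0)
    stop("spike_interval_s (second-peak offset) must be > 0 for class ",
         class_label)

  # class-shape defaults ------------------------------------------------------
  directLanding <- class_label %in% c("3c", "W1", "W2", "W3") ||
    (protocol == "wound" && class_label %in% c("2a", "2b"))
  if (is.null(plateau_onset_s)) {
    plateau_onset_s <- if (directLanding) peak_time_s
      else if (class_label %in% c("2a", "2b"))
        peak_time_s + 1.5 * decay_tau_s * log(2)
      else if (class_label == "2c") 1500
      else if (class_label == "W5") 850
      else if (class_label == "W4") peak_time_s + spike_interval_s + 150
      else peak_time_s
  }
  # a landing plateau is already established when the decay reaches it; only
  # plateaus that build up after a return towards baseline ramp in visibly
  if (is.null(plateau_tau_s)) plateau_tau_s <- if (directLanding) 1 else 90
  if (is.null(plateau_end_s))
    plateau_end_s <- if (class_label == "W2") 1100
      else if (class_label == "W3") 1200
      else if (class_label == "3c") 1000
      else Inf
  if (is.null(second_peak_time_s))
    second_peak_time_s <- if (secondPeak) peak_time_s + spike_interval_s
                          else NA_real_
  if (is.null(spike_start_s))
    spike_start_s <- if (class_label == "3c") plateau_end_s + 150
      else if (spiking) peak_time_s + 300
      else NA_real_
  if (is.null(spike_end_s))
    spike_end_s <- if (class_label == "2c") plateau_onset_s - 120
      else if (spiking) Inf
      else NA_real_
  if (class_label == "W3" && plateau2_level <= 0)
    stop("class W3 requires plateau2_level > 0")

  p <- list(class_label = class_label, protocol = protocol,
            baseline = baseline, peak_amplitude = peak_amplitude,
            peak_time_s = peak_time_s, rise_tau_s = rise_tau_s,
            decay_tau_s = decay_tau_s, plateau_level = plateau_level,
            plateau2_level = plateau2_level,
            spike_interval_s = spike_interval_s,
            spike_amplitude = spike_amplitude, noise_sd = noise_sd,
            plateau_onset_s = plateau_onset_s, plateau_tau_s = plateau_tau_s,
            plateau_end_s = plateau_end_s,
            plateau_end_tau_s = plateau_end_tau_s,
            spike_start_s = spike_start_s, spike_end_s = spike_end_s,
            second_peak_time_s = second_peak_time_s,
            event_width_s = event_width_s)
  class(p) <- "TransientParams"
  p
}

#' @export
print.TransientParams <- function(x, ...) {
  cat(sprintf(
    "TransientParams [%s, %s]: A=%.3g @ %.3g s, C=%.3g, C2=%.3g, D=%.3g s, noise=%.3g\n",
    x$class_label, x$protocol, x$peak_amplitude, x$peak_time_s,
    x$plateau_level, x$plateau2_level, x$spike_interval_s, x$noise_sd))
  invisible(x)
}

# Raised-cosine bump of unit height centred at `centre` with full width `w`.
.bump <- function(s, centre, w) {
  out <- numeric(length(s))
  inside <- abs(s - centre) <= w / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * (s[inside] - centre) / w))
  out
}

# Noiseless waveform at times `times` (s from recording start), stimulus at
# `stimulus_time_s`. Vectorised over the grid.
.evalTransient <- function(p, times, stimulus_time_s) {
  s <- times - stimulus_time_s
  pk <- numeric(length(s))

  if (p$peak_amplitude > 0) {
    s_pk <- p$peak_time_s
    s_on <- max(0, s_pk - 3 * p$rise_tau_s)
    if (s_pk - s_on < 1e-9) {
      pk[s >= s_pk] <-
        p$peak_amplitude * exp(-(s[s >= s_pk] - s_pk) / p$decay_tau_s)
    } else {
      denom <- 1 - exp(-(s_pk - s_on) / p$rise_tau_s)
      ris <- s >= s_on & s <= s_pk
      pk[ris] <- p$peak_amplitude *
        (1 - exp(-(s[ris] - s_on) / p$rise_tau_s)) / denom
      dec <- s > s_pk
      pk[dec] <- p$peak_amplitude * exp(-(s[dec] - s_pk) / p$decay_tau_s)
    }
  }

  pl <- numeric(length(s))
  if (p$plateau_level > 0) {
    o <- p$plateau_onset_s
    pl <- p$plateau_level *
      ifelse(s >= o, 1 - exp(-(s - o) / p$plateau_tau_s), 0)
    if (is.finite(p$plateau_end_s)) {
      e <- p$plateau_end_s
      aft <- s > e
      level_at_end <- p$plateau_level *
        (if (e >= o) 1 - exp(-(e - o) / p$plateau_tau_s) else 0)
      pl[aft] <- p$plateau2_level + (level_at_end - p$plateau2_level) *
        exp(-(s[aft] - e) / p$plateau_end_tau_s)
    }
  }

  v <- p$baseline + pmax(pk, pl)

  if (!is.na(p$second_peak_time_s) && p$spike_amplitude > 0)
    v <- v + p$spike_amplitude * .bump(s, p$second_peak_time_s,
                                       p$event_width_s)

  if (p$class_label %in% .SPIKING_CLASSES &&
      p$spike_interval_s > 0 && p$spike_amplitude > 0) {
    st <- .spikeTimes(p, max(s))
    for (ct in st) v <- v + p$spike_amplitude * .bump(s, ct, p$event_width_s)
  }
  v
}

# Spike centre times (s after stimulus) implied by the parameters, clipped to
# the recording.
.spikeTimes <- function(p, s_max) {
  if (!p$class_label %in% .SPIKING_CLASSES || p$spike_interval_s <= 0 ||
      is.na(p$spike_start_s)) return(numeric())
  hi <- min(p$spike_end_s, s_max - p$event_width_s / 2, na.rm = TRUE)
  if (hi < p$spike_start_s) return(numeric())
  seq(p$spike_start_s, hi, by = p$spike_interval_s)
}
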