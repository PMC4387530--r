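---
title: "Models and methods behind CaSignatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind CaSignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaSignatures)
```

CaSignatures analyses calcium imaging of confluent epithelial monolayers at
single-cell resolution: segmentation of (nearly) every cell in the field,
ratiometric trace extraction, signature metrics, shape classification, and
wound-distance statistics. This vignette explains the models and procedures
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The measurement model

Cells are loaded with two calcium-sensitive dyes whose fluorescence
responds reciprocally to calcium binding: one channel brightens, the other
dims. Their ratio cancels per-cell differences in dye loading and
illumination, so the ratio trace of each cell is a loading-independent
readout of its cytosolic calcium. The sentence ordering in descriptions of
the dye pair is ambiguous about which channel rises; the renderer therefore
exposes a `dye_polarity` option and defaults to green-increasing /
red-decreasing with ratio = green/red. Either polarity gives a ratio that
is monotone in calcium; only the labelling differs.

In the synthetic renderer the two channels of a cell with calcium elevation
$c(t)$ (trace value above its baseline) scale as $\sqrt{1+c}$ and
$1/\sqrt{1+c}$, so the pixelwise ratio equals $1+c$ exactly and the per-cell
brightness factor (lognormal, s.d. 0.25, emulating uneven dye uptake)
cancels. This makes noiseless single-cell renders round-trip their input
transients through the full extraction path.

## Segmentation

The algorithm has three phases.

1. **Pre-processing.** The first and last frames of both channels are
   summed and min–max normalized (so both early- and late-responding cells
   are bright), Gaussian-blurred (`blur_sigma_px`, default 2), globally
   masked (`mask_threshold`, default 0.05 of the normalized range), and
   sharpened by local-mean suppression: a pixel dimmer than
   `localmean_fraction` (0.7) of the mean of its
   `localmean_window_px` (25 px) neighbourhood is zeroed. The suppression
   step darkens the shallow ridges between adjacent cells.
2. **Iterative seeded extraction.** The brightest remaining pixel seeds an
   8-connected region grown down to `roi_threshold_fraction` (0.5) of the
   seed intensity, restricted to `max_radius_px` (30) of the seed — the
   candidate ROI. The same growth at the lower `halo_threshold_fraction`
   (0.3) defines a halo; ROI and halo are zeroed in the working image,
   which is what separates touching neighbours. Candidates outside
   [`min_size_px`, `max_size_px`] = [50, 2000] px are rejected (their
   pixels still zeroed). Extraction stops at `max_roi_count` or when the
   residual maximum falls below the mask threshold, so it terminates
   without user input on sparse images. The "adaptive threshold" is
   deliberately interpreted as seed-relative region growing — the threshold
   scales with each cell's own brightness — rather than a gradient
   watershed; ties between equal maxima break to the lowest row, then
   column, making the whole procedure deterministic.
3. **Review.** `reviewROIs()` deletes listed ROI ids, a programmatic
   stand-in for interactive checking; remaining ids are untouched.

Defaults were calibrated on rendered synthetic monolayers at a realistic
packing (~120 cells of ~25 µm diameter in a 512 × 512 px field at
0.65 µm/px) to exceed 96% recall with ≥ 95% precision; `scoreSegmentation()`
computes recall/precision/centroid-RMSE by greedy one-to-one centroid
matching, which the test suite verifies against exhaustive assignment on
small instances.

## Denoising and signature metrics

Traces are denoised by a slope-gated local average: a sample whose central
difference across the window (`denoise_window_s`, 5 s) is below
`slope_threshold` (0.01 a.u./s) is replaced by its window mean; rapidly
changing samples pass through unchanged, so quiescent stretches are
smoothed without blunting peaks or spikes.

The metric stage applies the denoiser twice before measuring. With trace
noise at realistic levels, the slope estimate itself is noisy, so a single
pass leaves a large fraction of flat-region samples untouched; those raw
samples then systematically inflate any maximum-based reading. A second
pass averages them (their neighbours are now smooth, so their slope
estimate drops below the gate). Measurements are further taken from a 5-s
moving average, with three refinements, each removing a specific
noise-driven bias while staying exact on clean data:

- **Apex fit.** The initial peak height is the vertex of a quadratic
  fitted to the *raw* samples within ±4 s of the located maximum. A plain
  noisy maximum is biased upward by extreme-value selection; a smoothed
  maximum is biased downward by blunting; the fitted vertex has neither
  bias (to ~1%). The reported peak time is the raw-sample argmax near the
  located maximum, which is exact for noiseless traces.
- **Two time scales.** The rapid initial peak is sought inside the
  initial-response window (`initial_window_s`, 10 min after the stimulus,
  matching the early-response window used for wound classification).
  Delayed and sub-threshold responses are instead measured on a 30-s
  smoothing of the whole post-stimulus trace — resolution matched to their
  time scale, which keeps the "peak" of a non-responder near zero instead
  of the maximum of its noise.
- **Persistence and masking.** The FWHM down-crossing (first fall below
  baseline + half the peak) and the return-to-baseline test must persist
  for 15 s, so a single noise excursion cannot end them early; plateau
  medians exclude ±120 s around detected spikes, so a spiking tail does
  not masquerade as a shallow plateau.

Conventions: the half-maximum reference is baseline-relative
(baseline + A/2), the standard FWHM convention; FWHM is zero by definition
when no measurable peak exists (`response_threshold`, 0.25 a.u.), and
equals recording length minus peak time when the trace never falls to
half-maximum (high sustained plateaus); the plateau estimator is the median
of the final third of the recording (robust to residual spikes), with a
dual-plateau detector that scans candidate change points for a sustained
downward step ≥ `step_threshold` (0.15 a.u.) between two flat levels both
above `plateau_threshold` (0.12 a.u.); spikes are local maxima after the
initial response with prominence ≥ `spike_prominence` (0.18 a.u.),
separated by ≥ 120 s, and required to be *discrete* — the elevation above
half their prominence must last ≤ 240 s, which distinguishes a spike from
a plateau segment. Internally everything is in seconds; reported peak time
and FWHM are in minutes and spiking rate in s⁻¹.

## Classification

The fourteen classes are assigned by a decision tree over the epoch
structure of the denoised trace:

- no measurable peak or plateau → **1a** (non-responding);
- onset latency (stimulus to half-peak on the rising edge) above
  `rapid_latency_s` (120 s) → slow: sustained level → **1b**; decayed to a
  plateau well below the peak → **W1** (wound); returned to baseline →
  **1c**. Latency, not peak time, decides "rapid": a cell whose *second*
  peak dominates can have a late peak time yet an immediate onset, which is
  how rapid-onset spiking classes can show late mean peak times.
- rapid onset, repeated spikes: ending in an extended terminal plateau
  (≥ 5 min) → **2c**; after a mid plateau between peak and first spike →
  **3c**; from baseline → **3b**;
- rapid onset, exactly one discrete second peak: ending in a plateau →
  **2b**, or **W4** when the trace first returned to baseline (wound);
  otherwise → **3a**;
- rapid onset, no further events: sustained dual plateau → **W3** (wound);
  terminal plateau reached directly → **2a**, or **W5** after a return to
  baseline (wound); a mid plateau that later decayed → **W2** (wound) /
  **2a** (ATP); bare peak–baseline → **3a** family (ATP) / **W5** with a
  near-zero plateau (wound).

The tree is total: every input receives exactly one class, and the
secondary → primary grouping (slow/absent, peak–plateau, peak–spiking for
agonist; early-response slow / peak–plateau / peak–baseline for wound)
follows the published taxonomy. Spiking under the wound protocol
contradicts the observation that wounded monolayers do not spike; it is
still classified (2c/3b/3c) but flagged with a warning. The
2c-versus-3b boundary ("ends in an extended plateau") uses a 5-minute
minimum terminal plateau — a convention, since no threshold is published.

With default thresholds, 100% of noiseless synthetic transients and ≥ 99%
(agonist) / ≥ 95% (wound) of transients at the default noise level recover
their generating class.

## Spatial statistics

Distances are measured from ROI centroids (declared in output metadata; the
alternative, nearest boundary pixel, is not used) to the wound-edge
polyline, scaled by the pixel size. The nominal proximal/distal split is
strict: proximal means < 100 µm, so a cell at exactly 100 µm is distal; the
threshold sweep instead compares ≤ x against > x for x = 10…400 µm in 10 µm
steps, each convention as its source states it. Mann–Whitney U uses
midranks, an exact two-sided tail for pooled samples ≤ 12 without ties, and
otherwise the normal approximation with tie and continuity corrections.
Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`) is followed by
Dunn z-statistics on mean ranks with Bonferroni adjustment over all pairs —
the common implementation of "Dunn's multiple comparisons post-test".

## The synthetic generator

Waveforms are built from a baseline, an initial peak (exponential rise to
the peak time, exponential decay), a plateau (exponential ramp, optionally
ending in a decay to baseline or a relaxation onto a second level), one
optional discrete second peak, and a raised-cosine spike train; the peak
and plateau combine through their pointwise maximum, so the transition from
a partial return toward baseline onto a rising plateau is monotone and is
never mistaken for a discrete spike. This family was chosen for
differentiability and parameter identifiability; published transient shapes
are verbal/pictorial, so the defining predicates of each class (onset
latency, epoch structure, level margins) are what the samplers guarantee,
with amplitude clips giving each predicate a margin against noise.

Default conditions mirror the imaging protocol: 1 frame/s sampling, 35 min
of agonist exposure (45 min post-wound with the first 10 min as the early
window), stimulus at 60 s, 512 × 512 px fields at 0.65 µm/px (a ×20
objective convention — pixel size, field size and bit depth are not
published facts), ~120 cells per agonist field and ~250 surviving cells per
wounded field (density 2600 cells/mm²), trace noise s.d. 0.05 a.u., and
imaging background/read/shot noise of 0.08/0.02/0.01 a.u. Class mixtures
come from the pooled published replicate counts (agonist) and from the
published proximal/distal group percentages (wound; the within-group split
across secondary classes is a convention, since the per-class wound counts
are not machine-readable in the source). Amplitude and timing moments
follow the published per-class and proximal/distal summary tables, drawn
lognormally by moments for nonnegative quantities. Two notable generator
choices: agonist peak–plateau classes use a *delayed* plateau onset so the
peak's FWHM is finite even when the plateau exceeds half the peak (the
published class-2 means — FWHM 3.92 min with plateau 0.79 against peak
1.04 — are only mutually consistent if the trace passes below half-maximum
before the plateau establishes), and the "slowly rising" class sags very
slowly (decay τ = 2500 s) instead of holding a perfectly flat level, so its
maximum is identifiable.

What the generator does **not** emulate: photobleaching, cell migration
during the recording, optical point-spread, out-of-focus light, and
cell-to-cell signalling correlations (cells respond independently given
their class and distance). Passing tests therefore demonstrate that the
pipeline recovers what this model generates — parameter recovery,
segmentation coverage, mixture recovery, spatial contrasts — not that it is
robust to every artefact of real recordings.

## Numerical choices and degenerate inputs

Seeds make every generator and the full pipeline bit-reproducible
(`withr::with_seed`, so the caller's RNG stream is untouched). Constant
images normalize to all-zeros; constant features scale to zero with a
degeneracy flag; empty measurement windows return zeroed metrics with
`has_peak = FALSE`; a wound run without geometry skips the spatial stage
with a warning, leaving earlier outputs intact; a sweep threshold with
fewer than 3 cells on either side yields `NA`. The ratio denominator is
floored at 0.02 a.u. because noise can take a background-dominated edge
pixel to zero. TIFF export scales each channel into [0, 1] (the format's
storage range) and records the scale factors in a YAML sidecar that the
reader undoes.

## Problem sizes used in the test suite

The suite validates metric recovery on 150 cells per primary class at 1 Hz
sampling, mixture recovery on a 360-cell population, the wound contrast at
the published group sizes (76 proximal / 178 distal), and segmentation on a
full 512 × 512 px render of ~120 cells; the end-to-end pipeline tests use
smaller fields (128–192 px, 9–30 cells) and coarser sampling, which
exercises every stage while keeping renders light. These sizes are the
package's own validation design.

## Known limitations

- The classifier's thresholds are calibrated on the synthetic suite; real
  recordings with different noise spectra or drifting baselines may need
  retuned `metricParams()`.
- Cells are assumed stationary (no tracking across frames).
- The wound-side test in `distanceToWound()` assumes a y-monotone edge
  polyline (true for the synthetic vertical scratch).
- Peak times of sustained, slowly rising responses are intrinsically
  ill-posed under noise: the trace is nearly flat at its maximum, so the
  reported time carries a wide uncertainty even though the height is
  stable.
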