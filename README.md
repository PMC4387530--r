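# CaSignatures

Automated, unbiased analysis of single-cell calcium transients in confluent
epithelial monolayers.

When a cultured epithelial sheet (the exemplar here is normal human
urothelium) is stimulated — either by perfusing the purinergic agonist ATP
over the whole layer, or locally by scratching away a strip of cells — each
cell answers with its own cytosolic calcium transient. Conventional analysis
averages the field or hand-picks a few conspicuous cells, which biases the
result toward strong responders. CaSignatures instead segments essentially
*all* cells from a two-channel ratiometric time-lapse recording, extracts one
denoised trace per cell, reduces each trace to a small set of signature
metrics, classifies every cell into a fourteen-class taxonomy of transient
shapes, and relates those signatures to the distance from the wound edge.

The package is for cell biologists and modellers who need per-cell response
statistics from calcium imaging of epithelial sheets, and for anyone who
wants a fully synthetic, ground-truthed test bed for such pipelines.

## What it computes

**Segmentation.** The first and last frames of the red and green dye
channels are summed and min–max normalized, blurred, globally masked, and
sharpened by local-mean suppression (pixels dimmer than a fraction of their
neighbourhood mean are zeroed, carving borders between adjacent cells).
ROIs are then extracted iteratively: the brightest remaining pixel seeds an
8-connected region grown down to a fraction *f*<sub>roi</sub> of the seed
intensity within a maximum radius; a second, lower-threshold region
(*f*<sub>halo</sub> < *f*<sub>roi</sub>) forms a "halo" that is stripped to
separate neighbours; candidates outside a size window are rejected. On
rendered synthetic monolayers this recovers ≥ 96% of cells.

**Signature metrics** (per cell, from the green/red ratio trace after
slope-gated denoising):

- baseline *b* (pre-stimulus mean) and initial peak height *A* above it,
  with the peak time;
- FWHM *B*: time from the peak until the trace first falls below
  *b* + *A*/2 (zero, by definition, when there is no measurable peak);
- plateau height *C*: sustained late elevation above baseline (median of
  the final third, spike-masked), with a second level for dual-plateau
  responses;
- spike interval *D* / spiking rate 1/mean(inter-spike interval) for cells
  that enter an oscillatory mode.

**Classification.** A rule-based decision tree over the post-peak epoch
structure assigns each cell one of nine agonist-protocol classes
(1a–1c slow/absent, 2a–2c rapid peak then plateau, 3a–3c rapid peak then
spiking) or, after wounding, the four shared classes plus five
wound-specific ones (W1–W5, including dual-plateau responses); populations
are tabulated per replicate with mean ± s.e.m. primary-group percentages.

**Spatial statistics.** Distances from ROI centroids to the wound-edge
polyline, the proximal/distal split at 100 µm, two-tailed Mann–Whitney *U*
tests (exact for small tie-free samples, tie- and continuity-corrected
normal approximation otherwise), a 10–400 µm threshold sweep of *p*(x), and
Kruskal–Wallis tests with Dunn's Bonferroni-adjusted post-hoc comparisons.

**Synthetic data.** A first-class module generates ground-truth cell
layouts, per-class transient waveforms (piecewise exponential peaks and
plateaus plus raised-cosine spikes), and rendered two-channel image stacks
in which the two dyes respond reciprocally to calcium so that their ratio
is exactly 1 + Δcalcium. Every stage of the pipeline is validated against
this ground truth.

## Worked example

Generate a 360-cell synthetic agonist-perfusion population, classify it,
and tabulate the classes:

```r
library(CaSignatures)
pop   <- makePopulation(atpClassMixture(), n = 360, protocol = "ATP", seed = 1)
cells <- classifyPopulation(pop$traces, protocol = "ATP")
tabulateClasses(data.frame(replicate = 1, secondary = cells$secondary), "ATP")
#> ClassTable (ATP protocol, 1 replicate)
#>
#>       1
#>   1a 30
#>   1b 27
#>   1c 11
#>   2a 95
#>   2b 13
#>   2c 21
#>   3a 14
#>   3b 81
#>   3c 68
#> primary-group percentages (mean +- s.e.m.):
#>   1               18.9 +- 0.0%
#>   2               35.8 +- 0.0%
#>   3               45.3 +- 0.0%

head(cells[, c("peak_height", "peak_time_min", "fwhm_min",
               "plateau_height", "spike_rate_per_s", "secondary")], 5)
#>  peak_height peak_time_min fwhm_min plateau_height spike_rate_per_s secondary
#>        1.225         1.150    3.667          0.536            0.000        2a
#>        0.910         1.217    4.633          0.789            0.000        2a
#>        0.800         1.317    0.817          0.016            0.002        3c
#>        0.877         1.133    4.033          0.577            0.000        2b
#>        1.085         0.917    1.400          0.000            0.001        3b

mean(cells$secondary == pop$truth$secondary)
#> [1] 0.9916667
```

Each row is one cell: peak height and plateau height in arbitrary ratio
units above baseline, peak time and FWHM in minutes after the stimulus,
spiking rate in s⁻¹, and the assigned secondary class. 99% of cells recover
their generating class at the default noise level.

The full image pipeline (synthetic render → segmentation → traces →
metrics → classes → spatial statistics) runs through one call:

```r
cfg <- pipelineConfig(protocol = "wound", source = "synthetic", rng_seed = 1)
bundle <- runPipeline(cfg, output_dir = "wound-run")
```

A thin command-line front end with per-stage subcommands (`simulate-atp`,
`simulate-wound`, `segment`, `trace`, `metrics`, `classify`, `spatial`,
`run`, `report`) lives at `inst/scripts/ca-pipeline.R`.

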