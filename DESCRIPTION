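Package: CaSignatures
Title: Automated Analysis and Classification of Calcium Transients in
    Epithelial Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated pipeline for unbiased single-cell analysis of
    calcium transients in confluent epithelial monolayers imaged with
    reciprocal ratiometric dyes. Provides iterative seeded region-growing
    segmentation with halo stripping to delineate nearly all cells in a
    field, ratiometric trace extraction, slope-gated denoising, signature
    metrics (initial peak height and time, full-width half-maximum,
    plateau heights, spike rate), a rule-based classifier covering the
    fourteen transient classes observed under agonist perfusion and
    scratch wounding, and rank-based spatial statistics relating
    signatures to wound proximity (Mann-Whitney threshold sweeps,
    Kruskal-Wallis with Dunn post tests). A synthetic-data module renders
    ground-truth monolayers and transients so every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification, TimeCourse
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
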