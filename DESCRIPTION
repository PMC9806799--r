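Package: trimcycif
Title: Single-Cell Image Analysis of Cell-Resealing Trim-Away with Cyclic
    Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of microscopic image-based single-cell
    quantification of antibody-mediated targeted protein degradation
    (Trim-Away) delivered by streptolysin-O cell resealing. Provides a
    synthetic cyclic-immunofluorescence image generator with per-cell ground
    truth (heterogeneous permeabilization, delivered antibody, TRIM21 and
    target abundance, saturating degradation kinetics, inter-round stage
    drift, bleaching carryover, shot and read noise), translation
    registration of staining rounds by phase correlation on the nuclear
    channel, nuclear segmentation with constrained label thickening into
    cell and cytosol regions, per-cell intensity quantification and
    colocalization, delivery-marker gating, top-percentile filtering,
    knockdown estimation with bootstrap intervals, condition comparisons,
    and t-SNE embedding of per-cell features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    Rtsne,
    jsonlite,
    methods,
    stats,
    tiff,
    tools,
    utils
Suggests:
    cluster,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
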