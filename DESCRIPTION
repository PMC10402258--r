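Package: morphoscale
Title: Multi-Scale Neuronal Morphometry from Skeletons, Volumes and
    Regional Density Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for multi-scale quantification of
    neuronal morphology in a common atlas space. Covers SWC skeleton
    input/output and classical morphometric (L-Measure style) features;
    seeded synthetic generators for toy atlases, branching morphologies,
    image volumes and regional neurite-density matrices; image-domain
    detectors for neurites (anisotropy salience), somas (gray-scale
    distance transform plus mean-shift refinement) and intensity/radius
    profiles; a consensus-merge and five-filter curation pipeline for
    locally traced dendrites; brain-region co-occurrence module
    detection; dendritic microenvironment construction with mRMR
    feature selection; full-morphology typing by spatially tuned
    spectral clustering; sub-neuronal arbor, tract and hub analysis;
    axonal bouton detection and statistics; and cross-scale
    diversity-and-stereotypy (DS) matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    e1071,
    igraph,
    jsonlite,
    mclust,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
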