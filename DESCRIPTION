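Package: closecontacts
Title: Quantitative Analysis of T-Cell Close Contacts in TIRF Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying microvillar close contacts formed by
    T cells on glycocalyx-bearing supported lipid bilayers, imaged by total
    internal reflection fluorescence (TIRF) microscopy. Provides a synthetic
    TIRFM video generator (Gaussian point-spread-function rendering, pixel
    binning and an EMCCD noise model), close-contact segmentation by
    Laplacian-of-Gaussian filtering with hysteresis thresholds,
    spatiotemporal watershed labelling of cell footprints, calcium-response
    tracking and triggering classification, local enrichment and exclusion
    statistics, single-bound-ligand counting, and supporting statistical
    models (Kaplan-Meier stage-transition curves, constrained dose-response
    fits, fluorescence correlation spectroscopy density estimation and
    z-stack surface-area measurement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    survival,
    minpack.lm,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization
RoxygenNote: 7.3.3
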