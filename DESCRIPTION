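Package: meltID
Title: Body-Fluid Identification from High-Resolution Melt Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplex high-resolution melt (HRM)
    assays that identify forensically relevant body fluids from
    fluid-specific mRNA markers. Provides marker and panel registries with
    published melting-temperature (Tm) windows, simulation of multiplex
    melt curves with realistic artifacts, Savitzky-Golay derivative melt
    plots, threshold-based peak calling with broad-hump rejection,
    Tm-window marker classification with genomic-DNA contamination and
    mixture flags, and donor-cohort specificity summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'melt-curve-set.R'
    'signal-processing.R'
    'peak-calling.R'
    'marker-classification.R'
    'reporting.R'
    'cli.R'
    'meltID-package.R'
    'panel-registry.R'
    'synthetic-melt.R'
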