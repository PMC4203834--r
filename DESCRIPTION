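Package: platesort
Title: Processing, Quality Control and Visualization of Large-Particle
    Flow Cytometry Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads, filters, normalizes, summarizes, statistically tests
    and visualizes per-object data from COPAS and BioSorter large-particle
    flow cytometers sampling 96-well microtiter plates. Provides dialect
    detection and round-trip I/O for the instruments' tab-delimited
    per-object format, hard size/optical-density cutoffs and a trainable
    support-vector-machine bubble classifier, per-length normalization of
    optical channels, per-well summary statistics with well removal and
    filling, edge-effect detection via the two-sided Wilcoxon rank-sum
    test, within- and between-plate trait correlation matrices,
    dose-response summarization by strain, plate-grid figure preparation
    and rendering, and a seeded synthetic-plate generator for calibrated
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'filtering.R'
    'io.R'
    'fixtures.R'
    'methods-accessors.R'
    'platesort-package.R'
    'stats-ranksum.R'
    'stats-plate.R'
    'summarize.R'
    'utils.R'
    'viz-prep.R'
    'viz-render.R'
    'wells.R'
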