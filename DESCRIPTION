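Package: amdorap
Title: Accurate m/z Detection for Comparative LC-Orbitrap Metabolic Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Preprocessing of high-resolution LC-orbitrap metabolomics runs
    that performs m/z peak picking and cross-sample alignment in a single
    grouping step. High-intensity centroid data points are collected from all
    samples, pooled and grouped by m/z closeness in parts per million, and
    the median m/z of each group is used to extract narrow-window ion
    chromatograms that are quantified as total-ion sums and as
    signal-to-noise gated peak areas after Gaussian smoothing. Also provides
    a molecular-formula mass calculus (monoisotopic masses, adduct m/z,
    ppm errors, tolerance-based annotation), a bundled tool-comparison
    fixture of fourteen identified compounds, and a synthetic LC-MS run
    generator with known ground truth for validation. Reads and writes
    centroid-mode mzML through 'mzR'.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
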