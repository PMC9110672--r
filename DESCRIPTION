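Package: pribin
Title: Bin-Based Pattern Analysis of High-Dimensional Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pattern recognition of immune cells (PRI) for mass and flow
    cytometry: reads FCS files, applies the arcsinh transform and sequential
    rectangular gating, partitions a two-marker plane into fixed-width bins,
    computes per-bin statistics (cell counts, mean signal intensity of a
    third marker over all cells and over z-positive cells) and quadrant
    frequency statistics, renders color-coded bin plots with dynamic or
    common intensity ranges, engineers per-sample features (maximum bin-MSI,
    quadrant percentages) for two-group comparison by exact Mann-Whitney U
    tests, and provides sample-level quality control (median-profile MDS,
    Ward clustering, non-redundancy score) together with a synthetic cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
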