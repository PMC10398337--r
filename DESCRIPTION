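Package: dalff
Title: Dynamic Amplitude of Low-Frequency Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic amplitude of low-frequency fluctuation
    (dALFF) analysis of 4D BOLD time series: windowed ALFF and its
    coefficient-of-variation map, voxelwise group inference with Gaussian
    random field cluster-level correction (plus a permutation oracle), L1
    k-means brain-state dynamics with occupancy/dwell/transition metrics,
    RBF-kernel SVM classification of cluster features, and normality-routed
    clinical correlation. Includes a synthetic BOLD cohort generator with
    known ground truth, a minimal NIfTI-1 reader/writer, and a command-line
    pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
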