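Package: fcgraph
Title: Functional-Connectivity Graph Analysis for Rodent Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for graph-theoretical analysis of
    resting-state fMRI functional connectivity in rodent absence-epilepsy
    studies: motion-based stable-epoch selection, Fourier low-pass
    filtering, global-signal regression, ROI time-series extraction,
    positive-only Pearson connectivity with Fisher-z group averaging and
    FDR edge significance, density thresholding, small-world metrics
    normalized against matched random networks, modularity community
    detection, hub scoring, network-based statistics with permutation
    inference, group-level edge and node statistics, and spectral
    detection of ~6 Hz spike-and-wave discharge epochs in optical calcium
    traces. Includes a seeded synthetic-data generator with planted
    community structure, homotopic coupling and group effects so that
    every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    car,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
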