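Package: speckleflow
Title: Laser Speckle Contrast Imaging Analysis for Intraoperative Cerebral
    Blood Flow and Stroke Lesion Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of laser speckle contrast imaging (LSCI)
    recordings from photothrombotic stroke experiments: spatial and temporal
    speckle-contrast estimation, inversion of the single-exposure speckle
    model to correlation time and relative cerebral blood flow, translational
    motion correction by subpixel cross-correlation, baseline-normalized
    hypoperfusion (CBF50) and hyperperfusion (CBF+) area time series,
    occlusion-success checks, threshold-planimetry lesion and infarct
    volumetry from T2-like and TTC-like slice stacks, and neurological
    severity score (NSS) group statistics.  Includes a physically grounded
    dynamic-speckle simulator (band-limited complex Gaussian fields with
    AR(1) temporal decorrelation) that provides ground-truth phantoms for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
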