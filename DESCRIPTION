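Package: SpermMotility
Title: Multistage Sperm Motility Tracking from Microscopy Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-assisted sperm analysis (CASA) pipeline for grayscale
    microscopy video. Detects motile sperm heads with a per-pixel adaptive
    Gaussian mixture background model whose background-ratio threshold is
    optimized automatically per sample, cleans foreground masks with
    morphological opening and closing, localizes heads via image moments with
    an elliptical-area filter, links detections across sampled frames by
    Euclidean distance and size-similarity gating, converts tracks to
    velocities and WHO motility classes (fast progressive, slow progressive,
    immotile), classifies samples as normal or abnormal by motile fraction,
    and scores detections against ground truth (accuracy, sensitivity,
    specificity). Includes a seeded synthetic-video generator with exact
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'background-model.R'
    'detection.R'
    'evaluation.R'
    'motility.R'
    'synthetic-data.R'
    'tracking.R'
    'video-io.R'
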