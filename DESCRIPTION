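Package: dualscreen
Title: Dual-Fluorescent Reporter High-Content Screening Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantification and screening analytics for dual-fluorescent
    transcription-factor reporter assays read out by high-content imaging
    and flow cytometry. Segments nuclei on a constitutive EGFP channel by
    isodata thresholding, applies border/abnormal/unseparated QC
    exclusions, and measures per-nucleus and per-well Tomato/EGFP
    intensities; computes plate-level Z-prime and fold-change robustness
    metrics and induction-kinetics summaries; calls activator and
    inhibitor hits from bimodal two-phase compound screens by z-scoring
    with EGFP-artifact exclusion and replicate intersection; fits
    four-parameter logistic dose-response curves for EC50 estimation;
    gates flow-cytometry events at the top percentile of a negative
    control; and quantifies iron-chelation activity curves. A
    synthetic-data generator with full ground truth (image fields, plates,
    screens, kinetics, dose series, flow events) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chelation.R'
    'dose-response.R'
    'dualscreen-package.R'
    'flow-gating.R'
    'hit-calling.R'
    'image-quant.R'
    'io.R'
    'plate-stats.R'
    'synthetic-data.R'
    'pipeline.R'
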