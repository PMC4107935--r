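Package: DixonMuscle
Title: Muscle Fat-Fraction Quantification from Dixon Water-Fat MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies muscle composition from chemical-shift (Dixon)
    water-fat magnetic resonance volumes of the lower leg: per-muscle
    intramuscular fat fraction (IntraMF), intermuscular fat of the whole
    muscle compartment (IMAT), the subcutaneous-fat-to-muscle volume ratio
    (SF/M), and a scan-rescan reproducibility metric, together with the
    group-comparison statistical battery used in cerebral palsy muscle
    studies.  Includes a synthetic leg-phantom simulator with controllable
    fat fractions, noise and T1-bias confounders, a four-point water-fat
    separation from multi-echo complex signals, NIfTI input/output, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
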