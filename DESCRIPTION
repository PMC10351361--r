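Package: adaptNTCP
Title: Toxicity Impact of Online-Adaptive Proton Therapy via NTCP Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework quantifying how setup-uncertainty reduction
    and adaptation to geometric changes lower normal tissue complication
    probability (NTCP) in online-adaptive head-and-neck intensity-modulated
    proton therapy. Provides synthetic voxel phantoms with per-fraction
    anatomical drift and residual setup error, an analytic spot-based proton
    dose engine with dose-influence matrices, minimax-robust and non-robust
    spot-weight optimization, partial spot-intensity re-optimization for
    daily online adaptation, deformable dose accumulation, six head-and-neck
    NTCP dose-response models (logistic, probit/gEUD and multivariable
    logistic), and per-mechanism delta-NTCP reporting with a configurable
    clinical-significance decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
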