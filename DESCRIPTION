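Package: aortamark
Title: Automatic Aortic Landmark Detection from Volumetric CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the five anatomical landmarks used in transcatheter
    aortic valve implantation (TAVI) planning - the three basal hinge points
    of the aortic valve leaflets (LCC, NCC, RCC) and the left and right
    coronary ostia (LCO, RCO) - from contrast-enhanced volumetric CT.
    Implements the full probability-map pipeline: isotropic resampling and
    ROI cropping, multi-radius spherical label masks, a pluggable detector
    backend with a Gaussian surrogate emulating a trained three-model
    ensemble, sliding-window prediction, probability-map fusion,
    threshold/cluster/centroid landmark extraction, aortic annular plane
    reconstruction with coronary ostium height measurement, a seeded
    synthetic aortic-root CT phantom generator, and agreement statistics
    (median/quartile error summaries, Wilcoxon signed-rank, Pearson
    correlation, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
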