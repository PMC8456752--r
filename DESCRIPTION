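Package: connectoscramble
Title: Scrambled-Edge Ensemble Classification of Wavelet Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sex (or any binary phenotype) classification of
    functional connectomes with stochastic scrambled-edge convolutional
    networks. Includes maximal-overlap discrete wavelet transform (MODWT)
    band decomposition of parcel time series into band-wise correlation
    matrices, a multivariate equal-width-binning confound balancer with
    Mann-Whitney certification, an ensemble trainer that aggregates
    overlapping held-out votes into ensemble AUROCs with a logistic-growth
    projection of the accuracy ceiling, guided Grad-CAM saliency mapped back
    to edge space, and paired include/exclude half-edge occlusion experiments
    on a-priori brain networks. A synthetic-cohort generator with plantable,
    band- and condition-specific edge effects makes the full pipeline
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
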