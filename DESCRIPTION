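Package: structofunc
Title: Predicting Individual Task-Activation Maps from Structural Brain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether structural brain imaging (T1w, T2w and
    multi-shell diffusion MRI) predicts individual-level task-fMRI activation
    maps. Provides a synthetic cohort generator with a planted, tunable
    structure-to-function signal; per-shell diffusion tensor fitting with MD
    and directionally-encoded FA feature channels; a residual 3D U-Net
    volumetric regressor trained with a domain-weighted mean-squared-error
    loss; permutation and per-vertex linear baselines; and an evaluation suite
    for subject identifiability (prediction-vs-actual correlation matrices,
    Kolmogorov-Smirnov diagonal tests), lateralization indices, ICC(3,1)
    test-retest reliability, and Gaussian plus two-gamma mixture thresholding
    of z-maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
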