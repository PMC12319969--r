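Package: fusireg
Title: Registration, Evaluation and Statistical Mapping for 2D Functional
    Ultrasound Vascular Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for aligning 2D power-Doppler-like vascular images across
    subjects and sessions: rigid registration with (1+1) evolutionary,
    cyclic one-dimensional and block-matching optimizers; non-rigid
    registration by the demons algorithm (with a diffeomorphic variant),
    cubic B-spline free-form deformation driven by adaptive stochastic
    gradient descent, total-variation-regularized local-correlation
    registration solved by ADMM, and piecewise-rigid patch registration;
    an evaluation suite (shifted normalized cross-correlation profiles,
    multi-scale SSIM, Haar-wavelet perceptual similarity, Otsu-binarized
    Dice overlap, Jacobian-determinant and folding analysis); genetic
    algorithm and grid-search hyperparameter optimization with rotational
    cross-validation; pixelwise statistical parametric mapping of percent
    signal change with false-discovery-rate control; and a seedable
    synthetic vascular phantom generator so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
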