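Package: seqfact
Title: Factorized Decoding of Motor Sequence Order and Timing from fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissociate independent representations of finger-press
    order and press timing in motor sequence production from their nonlinear
    integration, using multivoxel pattern analysis of condition-by-run beta
    patterns. Implements cross-classification fold construction with transfer
    across the non-decoded feature, Gaussian linear discriminant classification
    with shrinkage-regularized pooled covariance, run-wise marginal-pattern
    residualization for integrated decoding, binomial z-transformation of
    accuracies, searchlight and ROI aggregation, sign-flip permutation cluster
    inference along cortical cross-section profiles, first-level GLM design
    construction (preparation boxcar and constant-impulse production
    regressors convolved with a canonical HRF), behavioral press detection
    from force traces, interpress-interval and timing-error analysis, a
    points-based trial scoring scheme, and synthetic-data generators with
    known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
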