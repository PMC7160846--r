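Package: stickmvpa
Title: Searchlight Decoding of Tactile Stickiness Intensity from fMRI Beta Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivoxel pattern analysis of tactile stickiness intensity coding.
    Generates synthetic trial-wise fMRI beta series with planted multivoxel
    intensity codes, fits single-trial general linear models against a canonical
    double-gamma hemodynamic response, decodes three stickiness levels with a
    Gaussian Naive Bayes classifier inside a cubical searchlight (two-fold
    run-wise cross-validation within a touch condition, and cross-condition
    transfer decoding between skin and glove contact), performs random-effects
    group inference with a sign-flip max-cluster-size permutation threshold, and
    reports confusion matrices, fold-comparison t-tests and repeated-measures
    ANOVAs of perceived-stickiness ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
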