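Package: stylemkl
Title: Style-Regularized Multiple Kernel Learning with Least-Squares SVMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification for style-grouped data with a
    least-squares support vector machine trained over a learned convex
    combination of base kernels.  Kernel weights are optimized by a
    semi-infinite linear program solved with cutting planes, and a
    per-group affine "style" transformation of the feature space is
    learned jointly with the classifier by alternating optimization.
    The style maps are never materialized: the transformed Gram matrix
    is obtained from base kernel values alone via a closed-form
    expansion.  Includes three prediction rules (ignore style, apply a
    known group's style map, or extrapolate to an unseen style group
    through temporary labels and a refit), a synthetic stylized-data
    generator, an optional EEG preprocessing front-end based on kernel
    PCA, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    kernlab,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
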