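Package: mrifusion
Title: Slice-Decomposition Ensembles and Feature Reduction for Structural Brain MRI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary classification of co-registered, gray-matter
    segmented 3D brain MRI volumes, aimed at early diagnosis and prognosis of
    Alzheimer's disease. Implements decomposition of 3D volumes into RGB-like
    2D images (three slices per image, four orientation schemes, configurable
    inter-slice gap) feeding per-slice 2D classifier ensembles fused by the
    sum rule; an Aggregate Selection feature selector combining Fisher score,
    two-sample t statistics and sparse L1-regularized logistic regression
    through analytic-hierarchy-process comparison matrices; kernel partial
    least squares feature extraction; a linear support vector machine with
    Platt-scaled probability outputs; a patch-based 3D convolutional network
    trained from scratch; nested cross-validation with AUC evaluation and
    whole-volume versus inner-structure comparisons; and a synthetic
    brain-like cohort generator (NIfTI-1 in and out) so every pipeline stage
    is testable without access to restricted clinical repositories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
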