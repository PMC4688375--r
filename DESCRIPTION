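Package: scandecode
Title: Decoding Yes/No Answers from Single-Scan fMRI Activity Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying a brain-based binary communication scheme in
    which a participant answers yes/no questions by performing one of two
    sustained mental tasks while whole-brain BOLD fMRI is acquired. The
    package simulates the complete two-day block-design experiment
    (alternating task runs plus sentence/answer runs) with planted
    discriminative activation, implements the voxelwise clean-up chain
    (nuisance regression, discrete-cosine high-pass filtering, grand-mean
    scaling, day-level standardization) and Gaussian smoothing, performs
    univariate GLM contrast mapping with AR(1) prewhitening for split-half
    feature selection, trains linear support-vector classifiers on single
    scans with leave-one-run-out cross-validation, assesses significance
    with a balanced-block permutation test, and retrieves binary answers by
    majority vote over response-period scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
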