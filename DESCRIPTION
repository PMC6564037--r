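Package: mtlpop
Title: Population Analysis of Single-Neuron Recordings from the Human
    Medial Temporal Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-unit spike-train recordings from
    the human medial temporal lobe (amygdala, hippocampus, entorhinal and
    parahippocampal cortex) during repeated visual presentation of
    semantically categorised stimuli.  Implements a binwise rank-sum
    response screening criterion with Simes correction, per-region response
    probabilities with subsampling confidence intervals and Fisher exact
    category-preference tests, representational similarity analysis on
    baseline z-scored population vectors (1 - Pearson correlation distance,
    UPGMA clustering, classical multidimensional scaling, label-shuffling
    permutation inference), and dual-level population decoding (category
    generalisation to unseen exemplars and single-trial stimulus identity)
    with one-vs-all linear max-margin classifiers scored by Cohen's kappa.
    A Poisson spike-train generator with a graded semantic tuning-curve
    model supplies ground-truth synthetic sessions, and pixel-level
    image-similarity controls (Euclidean, MSE, PSNR, SSIM) rule out
    low-level confounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    vegan,
    optparse,
    data.table
Config/testthat/edition: 3
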