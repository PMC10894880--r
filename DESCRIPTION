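Package: slidefuse
Title: Two-Tier Whole-Slide-Image Classification via Patch-Likelihood
    Histogram and Bag-of-Words Fusion
Version: 0.1.0
Authors@R:
    person("slidefuse", "developers", email = "slidefuse@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a two-tier
    digital-pathology classification pipeline for H&E-stained whole-slide
    images (WSIs): tiling with background removal, Macenko stain
    normalization and RGB z-scoring; a convolutional patch classifier
    trained by transfer learning under paired cosine-decay learning-rate
    schedules (task head vs backbone); multi-instance fusion of per-patch
    likelihoods into case- or slide-level feature vectors through a
    patch-likelihood histogram (PLH) and a TF-IDF bag-of-words (BoW)
    pipeline; t-test feature filtering with grid-searched WSI-level
    classifiers (SVM, random forest, extremely randomized trees, gradient
    boosting, MLP); and an evaluation suite with DeLong AUC confidence
    intervals and paired tests, one-vs-rest micro/macro AUC, confusion
    matrices, decision-curve analysis, probability heatmaps and t-SNE
    embeddings. Ships a synthetic H&E-like cohort generator so the whole
    pipeline is exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    Rtsne,
    stats,
    utils
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
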