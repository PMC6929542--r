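Package: ddigip
Title: Drug-Drug Interaction Prediction with Gaussian Interaction Profile Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from a known-interaction
    network using a Gaussian interaction profile (GIP) kernel on interaction
    profiles and a regularized least squares (RLS) classifier, with a
    K-nearest-neighbour cold-start step that imputes initial interaction
    scores for drugs without known interactions from the Pearson similarity
    of binary chemical/biological/phenotypic feature vectors. Includes
    cross-validation and de novo (leave-one-drug-out) evaluation with
    rank-based AUC, a synthetic benchmark generator with latent drug groups,
    readers and writers for edge lists and feature tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
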