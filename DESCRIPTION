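Package: cdal
Title: Cross-Domain Active Learning for Sensor-Array Drift Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pool-based cross-domain active learning (CDAL) for gas-sensor
    array (electronic nose) drift compensation. Candidate samples from a
    drifted target batch are scored by a weighted combination of
    query-by-committee disagreement (summed pairwise Hellinger distance
    between committee posteriors) and the maximum mean discrepancy between
    the candidate and the source-domain mean embedding under a Gaussian
    kernel; the top-scoring samples are labelled and moved into the
    training set before the classifier is refit. Includes a Gaussian-kernel
    SVM chair with softmax committee members, KLD/JSD disagreement
    baselines, a loader/writer for LIBSVM-style per-batch drift files, a
    synthetic multi-batch drift-world generator, and an evaluation harness
    for long- and short-term drift protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
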