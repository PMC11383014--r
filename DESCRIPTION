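Package: lupine
Title: Deep Matrix Completion for Multi-Cohort TMT Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing protein quantifications in multi-cohort
    tandem mass tag (TMT) proteomics. Learns low-dimensional protein and
    sample embeddings that feed a multilayer perceptron to predict missing
    entries of a joint protein-by-sample log-intensity matrix, trained under
    an explicit missing-not-at-random (left-censored) partitioning regime and
    deployed as an ensemble of independently seeded models. Also provides the
    Perseus-style downshifted-Gaussian and column-minimum baseline imputers,
    accuracy metrics on held-out entries, paired differential-expression
    analysis with Benjamini-Hochberg correction, protein-complex co-expression
    checks, and a synthetic multi-cohort data generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
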