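Package: gsda
Title: Group-Specific Discriminant Analysis for Brain-Network Lateralization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting group-specific lateralization of brain
    functional networks with a dual-classification workflow.  A logistic
    discriminant regularized by a simplified Hilbert-Schmidt independence
    criterion (HSIC) learns group-specific left-versus-right hemisphere
    classifiers from intrahemispheric connectivity features; a group
    specificity index (GSI) quantifies how specifically a model generalizes
    to its target group; and a second-order classification stage identifies
    which connection weights differ between group-specific models.  Includes
    connectivity feature extraction (Pearson correlation, Fisher z,
    run averaging, hemisphere reordering, upper-triangle vectorization),
    subject-aware cross-validation partitions, a synthetic-data generator
    with planted lateralization effects, plain-text readers/writers and a
    small command-line interface, so the full workflow is testable without
    access-restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
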