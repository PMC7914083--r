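Package: matriplet
Title: Mahalanobis-Metric Triplet Learning for Medical Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metric-learning classifier for grayscale medical-style images and
    ordinal cytology-style tables. Couples a residual convolutional embedding
    network with spatial pyramid pooling to a learned Mahalanobis distance,
    trained with an improved ratio-form triplet loss plus a pairwise
    intraclass constraint by alternating stochastic gradient descent on the
    network weights and projected gradient descent of the metric matrix onto
    the positive semidefinite cone. Includes batch-hard triplet mining over
    K-class x L-image batches, a multi-round cross-modal attention memory
    encoder with generative and discriminative decoders, grayscale histogram
    equalization, and seeded generators for synthetic nodule-like images and
    Wisconsin-breast-cancer-style tabular records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
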