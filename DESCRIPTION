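Package: clinclust
Title: Robust Unsupervised Patient Stratification from Clinical Biomarkers
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates the robustness of unsupervised patient stratification
    built from classical blood biomarkers. Provides the four canonical
    pre-processing variants (raw, normal transform, Z-score, age-adjusted
    Z-score), three clustering algorithms (a CLICK-style graph clustering
    that may leave samples unclassified, k-means, and a batch-trained
    self-organizing map), homogeneity-separation cluster quality with
    dropout resampling, projection of training clusters onto a validation
    cohort via a feed-forward classifier, hypergeometric trait enrichment,
    and cross-cohort validated-enrichment accounting. Ships a synthetic
    cohort-pair generator with planted subgroups, age effects and
    trait-subgroup associations for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
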