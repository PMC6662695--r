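Package: enterocag
Title: Enterotype-Based and Co-Abundance Group Analysis of Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for enterotype-stratified analysis of genus-level gut
    microbiota abundance tables along the colorectal adenoma-carcinoma
    sequence. Implements threshold-rule enterotype classification from the
    relative abundances of Bacteroides and Prevotella, alpha-diversity
    comparison, rank-based differential abundance testing with a
    cancer-prevalence filter, co-abundance group (CAG) detection by
    hierarchical clustering of genus correlation matrices, stable-anchor
    correlation network comparison across disease groups, and chi-square
    contingency statistics for cohort covariates. A seeded synthetic-cohort
    generator with planted enterotype regimes, co-varying genus blocks and
    group-specific abundance shifts provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
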