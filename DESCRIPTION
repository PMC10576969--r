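Package: vmeassess
Title: Assessing Vulnerable Marine Ecosystems from Seafloor Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for designating Vulnerable Marine Ecosystems (VMEs) from
    single seafloor images. Provides a machine-readable registry of VME
    indicator taxa by regional fisheries management body with rank-aware
    lookup and cross-region consensus operations, readers and writers for
    per-image annotation tables, count-to-density conversion with area
    filtering, a deterministic short-circuiting decision flow chart mapping
    image evidence to FAO VME criteria, calibration statistics over expert
    Yes/Maybe/No labels (group summaries, one-way ANOVA, Tukey HSD,
    covariate regressions, density-threshold estimators), and an
    overdispersed negative-binomial annotation simulator for testing every
    pipeline stage without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
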