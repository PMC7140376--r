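Package: pathstrat
Title: Sequential Pathway Expression-Pattern Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumor cohorts by the relative expression patterns of
    small, functionally related transcript sets. Pathway-restricted expression
    vectors are normalized onto the unit hypersphere, embedded with t-SNE,
    clustered by Gaussian mixture models, and the resulting groups compared by
    Kaplan-Meier estimation and log-rank tests. The whole pipeline can be
    re-applied with a second pathway inside a chosen first-pass cluster
    (sequential profiling), or applied within groups cut from a
    whole-transcriptome dendrogram, to refine survival prediction. Includes a
    seeded synthetic-cohort generator with planted cluster structure and
    cluster-dependent exponential survival so every stage is testable without
    external data, plus a report writer and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rtsne,
    mclust,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
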