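Package: cagphases
Title: Phases of Somatic CAG-Repeat Expansion and Neurodegeneration in
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the cell-autonomous progression of Huntington's disease
    neurodegeneration from single-nucleus RNA-seq data paired with per-cell
    HTT CAG-repeat length measurements.  Provides per-cell somatic expansion
    statistics and their negative-binomial regression onto donor, cortical
    region and fine molecular identity; per-gene negative-binomial models
    with a hinge repeat-length covariate (phase C) and a logistic
    de-repression covariate (phase D); de-repression crisis analytics;
    identity-erosion enrichment; reference-normalized cell-survival
    estimation; and a stochastic two-phase repeat-expansion simulator with a
    ground-truth ledger for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
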