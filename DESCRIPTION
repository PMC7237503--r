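Package: ResistOmics
Title: Multi-Omics Analysis of Anti-Androgen Resistance Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analyses used in multi-omics studies
    of treatment-resistant prostate cancer: cross-condition differential
    signature selection on label-free proteomics matrices, natural-abundance
    correction and enrichment metrics for 13C isotope-tracing data, lipid
    shorthand parsing and saturation-class profiling, a hyperspectral Raman
    tissue-map QC and band-ratio pipeline, and expression-based survival
    stratification. A synthetic-data generator with planted ground truth
    makes every stage testable without access to raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
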