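Package: pcpgsomatics
Title: Somatic Variant Filtering, Signature Refitting and Clonal Metrics
    for Paraganglioma Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("A5", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a multi-sample
    tumour whole-genome study: two-of-three somatic variant consensus with
    panel-of-normals and reject:pass-ratio blacklists, structural-variant
    recurrence and read-support filters, SBS-96 catalog construction and
    non-negative least-squares refitting against reference mutational
    signatures, telomere content and telomere-variant-repeat statistics,
    GISTIC input preparation, percent-genome-altered and microsatellite
    instability scoring, and copy-number-aware variant read probabilities
    with a binomial-mixture subclone frequency estimator. A seeded
    synthetic-cohort generator provides ground-truthed fixtures for every
    stage, and a pipeline runner ties the stages together with a
    reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
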