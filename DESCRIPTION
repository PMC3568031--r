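Package: trionovo
Title: De Novo Variant Prioritization for Trio Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Filter-cascade prioritization of de novo candidate mutations in
    trio exome cohorts of sporadic disease. Implements sequential
    novelty/consequence/expression filtering with per-stage count reports,
    known-variant database matching under position-only or allele-aware
    semantics, cross-proband recurrence at the variant and gene level,
    gene-refocus re-analysis that bypasses the novelty filter, Mendelian trio
    classification of candidates, control-cohort screening, a confirmation
    oracle standing in for Sanger validation, Grantham physicochemical
    substitution distances, cross-species conservation scoring, and a seeded
    trio-cohort simulator with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
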