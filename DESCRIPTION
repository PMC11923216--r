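Package: fairlivestock
Title: FAIR and GDPR Reusability Assessment of Livestock-Sector Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the research reusability of routinely collected
    livestock-sector datasets from structured survey descriptions. Implements a
    twelve-criterion FAIR (Findable, Accessible, Interoperable, Reusable)
    compliance rubric and a two-criterion GDPR accountability rubric, grades
    survey-answer quality (completeness and coherence with a strict 75%
    threshold), harmonises two survey rounds with coherence-based conflict
    resolution, anonymises records via seeded random identifiers and field
    reclassification, and produces cohort characterisation and compliance
    summaries. Includes a seeded synthetic survey-cohort generator so the full
    pipeline is testable without access to any restricted survey deposit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
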