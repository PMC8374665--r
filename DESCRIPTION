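Package: ichomdq
Title: Data Quality Assessment of ICHOM Heart-Failure Visit Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-dimension data-quality assessment (uniqueness, consistency,
    completeness, temporal stability, correctness) for flat, visit-centered
    tables of ICHOM heart-failure outcome variables extracted from hospital
    electronic health records. Ships a machine-readable data dictionary for
    the 22-variable pilot schema, typed CSV parsing, a seeded synthetic
    generator of relational EHR sources with a ground-truth ledger of planted
    errors, a relational-to-flat ICHOM mapper that reproduces the duplication
    and zero-coding artifacts of date-matched left-outer-join extraction, and
    per-check scoring with findings export and JSON quality reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
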