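Package: emraudit
Title: Diagnosis Undercount Audits for Primary-Care EMR Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the undercounting of chronic-disease diagnoses that occurs
    when general-practice electronic medical record (EMR) data are summarised
    from coded diagnosis entries alone, ignoring clinically validated free-text
    entries. Given an EMR diagnosis extract and a curated phenotype dictionary
    (code lists, validated free-text terms, invalid code-term mappings), the
    package identifies active patients, counts patients per disease under the
    coded-only and the free-text-or-coded definitions, computes the percentage
    undercount with pooled two-proportion z-tests, and summarises
    between-practice variation. A seeded synthetic-cohort generator with
    ground-truth labels makes the whole pipeline testable without access to
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
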