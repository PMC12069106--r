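Package: fccmap
Title: Mapping Food Contact Chemicals to Evidence of Human Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step workflow for linking inventories of known food contact
    chemicals (FCCs) to evidence of their presence in humans. Step 1 matches
    chemicals by CAS Registry Number, InChIKey, or SMILES against human
    biomonitoring program analyte lists (with metabolite-parent pairing) and
    metabolome/exposome database listings, and resolves a per-chemical
    evidence status. Step 2 prioritizes chemicals absent from all step-1
    sources by their detection frequency in food contact material migrates
    and extracts, and classifies evidence from systematic literature
    extraction records. Chemicals are additionally tiered by concern using
    pooled GHS hazard classifications (CMR categories 1A/1B/2 and STOT RE
    categories 1/2). Includes strict readers and writers for all source
    tables, consolidated reporting (summary counts, group summaries, Sankey
    flow tables), and a seeded, quota-exact synthetic-universe generator so
    the whole pipeline is testable without access to the external source
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
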