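Package: tdassoc
Title: Target-Disease Association Scoring and Pharmacovigilance Signal
    Detection
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Validates target-disease evidence records against a shipped
    JSON schema, propagates evidence across a disease ontology up to
    therapeutic areas, aggregates evidence into association scores by
    normalized (weighted) harmonic sums, and detects significant
    drug-adverse-event pairs in spontaneous-report tables with a
    likelihood-ratio test calibrated by Monte-Carlo critical values.
    Ships a synthetic-data generator for ontologies, evidence sets and
    adverse-event report tables with planted structure, plus a
    reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
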