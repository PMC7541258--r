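Package: mrsynergy
Title: Master Regulator Activity and Synergy Analysis over Regulon Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers differential activity of master regulators (MRs) from
    gene-level differential-expression signatures and a regulon interactome
    (regulator, target, mode of regulation, likelihood), selects common top
    MRs across discovery datasets with rank-sum validation and an
    activity-expression consistency filter, tests MR pairs for synergy via
    the expression contribution to activity (ECA = DE x MOR) of shared
    versus unique regulons, and relates MR expression to clinical features,
    somatic mutation classes and overall survival. Includes synthetic-data
    generators with planted ground truth for benchmarking the whole
    pipeline, plus TSV/JSON import and export for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
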