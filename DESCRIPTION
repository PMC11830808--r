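Package: orphanscape
Title: Rare-Disease Therapeutic Landscape and Market Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the rare-disease (orphan drug) therapeutic
    ecosystem from portfolio and financial tables: ingestion and entity
    normalization of intervention records, a tripartite
    company-collaborator-disease network with company-knockout robustness
    simulation, per-company competitive and innovative index scoring,
    ODD versus non-ODD market segmentation and market-share analytics,
    confidence-scored drug-protein network construction and comparison,
    and a synthetic ecosystem generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
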