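Package: reachcalc
Title: Estimate the Reach of Social-Impact Products from Supply and Use Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts product supply-chain data (sales, distribution, or
    production-flow volumes with quality and post-production-loss
    adjustments) and consumer use patterns (daily amount and use frequency
    for fast-moving goods; users per unit and turnover for durable goods)
    into estimates of the number of individuals reached by a social-impact
    product over a defined period and area. Supports coverage-based
    estimation, consumer segmentation, population-subgroup allocation,
    razor-and-blade products, best/worst-case scenario bounds and
    one-parameter sensitivity sweeps, YAML/JSON configuration files with a
    structured assumptions ledger, dated supply-ledger CSV ingestion, and a
    command-line interface. Ships a fully worked fortified-rice case study
    for Brazil as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
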