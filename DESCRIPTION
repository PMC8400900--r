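Package: fopwarn
Title: Nutrient Profile Models and Front-of-Package Warning-Label Coverage
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule-engine pipeline for estimating how much of a packaged-food
    supply would carry "high-in" front-of-package warning labels under two
    nutrient profile models: the WHO South-East Asia Region (SEARO)
    category-specific model and the Chilean Warning Octagon (CWO) Phase 3
    model with its added-ingredient gating. Includes product-record ingestion
    with an auditable exclusion cascade, reconstitution of concentrates to an
    as-consumed basis, data-driven threshold tables, per-category coverage and
    warning-label-count reporting, and a seeded synthetic product-database
    generator with a biased-subsampling mode for studying selection-bias
    inflation of coverage estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
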