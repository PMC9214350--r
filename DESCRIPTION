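Package: ecdcea
Title: Cost-Effectiveness League Tables for Early Childhood Development Interventions
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for value-for-money comparison of early childhood development
    (ECD) interventions. Standardizes per-child intervention costs across
    countries and years (ingredients-based costing, consumer-price-index
    adjustment, wage re-referencing to a 2010 LMIC anchor), aggregates
    domain-specific Cohen's d effect estimates under configurable weight
    schemes (averaged, summed, custom), computes incremental
    cost-effectiveness ratios (ICERs) with interval-propagated 95%
    uncertainty ranges, and emits ranked league tables. Ships a bundled
    portfolio of 16 published early parenting and psychosocial stimulation
    intervention arms together with the published reference league tables,
    plus a synthetic portfolio generator for property testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
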