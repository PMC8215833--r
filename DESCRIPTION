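Package: hdwarm
Title: Weighted Association Rule Mining for Heart Disease Risk Rules
Version: 1.0.0
Authors@R:
    person("hdwarm", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines class-association rules for heart disease from
    categorical clinical records using weighted association rule mining
    (WARM). Computes per-feature strength scores from feature-selection
    occurrence counts (normalized feature weights, empirical value
    weights, and their product as total item weights), discretizes
    Cleveland-format records into clinical categories, mines frequent
    itemsets with an Apriori-style level-wise search, and scores
    antecedent-to-class rules by weighted support and weighted
    confidence. Includes a synthetic-data generator with controllable
    marginals and planted rules, rule ranking and summary reports, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
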