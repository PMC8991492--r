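Package: foodbench
Title: Benchmarking Food Industry Nutrition Commitments and Practices
Version: 0.1.0
Authors@R:
    person("Food Environment", "Benchmarking Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A reproducible pipeline for benchmarking the nutrition-related
    commitments and practices of food and beverage manufacturers,
    supermarkets and quick-service restaurants.  Products are classified
    under three nutrient-profile systems (Nutri-Score points model,
    WHO-Europe nutrient profile model for marketing to children, NOVA
    processing groups); company commitment sheets are aggregated into
    weighted BIA-Obesity domain scores; portfolio, promotion and
    outlet-accessibility performance indicators are computed; and the
    commitment-practice relationship is tested with rank-based statistics
    (Spearman correlation, Wilcoxon signed-rank and rank-sum tests, with
    exact small-sample p-values).  A synthetic-data generator with a
    tunable commitment-practice coupling parameter makes every stage
    testable without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
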