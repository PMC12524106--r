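Package: cuatree
Title: Decision-Tree Cost-Utility Analysis of Statin Dose-Escalation
    Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engine for two-stage decision-tree cost-utility models of
    lipid-lowering therapy with dose escalation: branch probabilities and
    costs, expected cost, utility and QALY aggregation, incremental
    cost-effectiveness ratios (ICER) with dominance and cost-effectiveness
    plane classification, willingness-to-pay banding against GDP-based
    thresholds, fail-state utility calibration, threshold price analysis,
    and one-way deterministic sensitivity analysis with tornado diagrams.
    Ships a fully parameterised Vietnam 2024 dyslipidemia scenario
    comparing pitavastatin, atorvastatin and rosuvastatin, and a seeded
    generator of synthetic scenarios for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
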