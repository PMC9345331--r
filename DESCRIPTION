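Package: caresim
Title: Microsimulation of the Financial Costs of Informal Care for Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A static-ageing microsimulation pipeline that projects the
    individual and national financial costs (lost income, lost income-tax
    revenue, extra welfare payments) of informal carers who are out of the
    labour force because they care for someone with a mental illness.
    Provides a seeded synthetic-microdata generator emulating survey-style
    carer files and a tax/transfer donor pool, generalized-regression
    (GREGWT-style) survey reweighting to projected demographic benchmarks,
    hot-deck statistical matching of economic attributes, real-growth
    indexation, a matched Monte Carlo counterfactual estimator with
    percentile confidence intervals, and national aggregation and reporting
    at five-yearly intervals from a 2015 base year to 2030.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
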