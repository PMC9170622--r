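Package: brcacua
Title: Cost-Utility Analysis of Risk-Reducing Strategies for BRCA1/2
    Mutation Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic Markov cohort model comparing risk-reducing
    strategies for women carrying a BRCA1 or BRCA2 mutation (intensified
    surveillance, prophylactic bilateral mastectomy, prophylactic bilateral
    salpingo-oophorectomy, their combination, and chemoprevention with
    Tamoxifen). Nine health states are expanded into tunnel states tracking
    years since cancer diagnosis; the engine produces lifetime discounted
    costs, quality-adjusted life years and life years, incremental
    cost-effectiveness ratios and dominance classifications, one-way
    (tornado) and probabilistic sensitivity analyses, and scenario analyses.
    Synthetic fixtures (a Gompertz-Makeham life table and a component-based
    cost schedule) allow the full pipeline to run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
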