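Package: equicost
Title: Equity Analysis of Household Time and Money Costs of Accessing Health Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the socioeconomic distribution of the costs
    patients incur to access and use primary health care, from exit-interview
    survey data. Builds an asset-based household wealth index by principal
    component analysis, computes tie-aware fractional wealth ranks and
    quintiles, and measures inequality in travel, waiting and consultation
    time and in transport and medical expenditure with equity gaps, equity
    ratios and concentration indices, stratified by residence, facility type
    and service type. Includes a synthetic exit-interview generator with
    closed-form concentration indices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
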