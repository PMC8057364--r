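Package: checap
Title: Catastrophic Health Expenditure Incidence and Determinants for
    Household Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the incidence of catastrophic health expenditure
    (CHE) from household survey microdata using the capacity-to-pay
    methodology: a food-share poverty line over an equivalence scale,
    subsistence expenditure, capacity to pay with the food-substitution
    rule for poor households, thresholded CHE indicators and threshold
    sensitivity analysis.  A determinants stage fits logistic models with
    average marginal effects and linear probability models with robust
    standard errors, with stepwise entry-removal covariate selection and
    contingency chi-square association tests.  Includes a synthetic
    household-survey generator with known ground-truth effects for
    validating the full pipeline when survey microdata cannot be shared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
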