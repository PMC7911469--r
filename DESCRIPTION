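Package: grsdiet
Title: Genetic Risk Scores and Gene-Diet Interaction Analysis for
    Nutrigenetic Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction of unweighted genetic risk scores (GRS) from
    candidate SNP panels, Hardy-Weinberg equilibrium screening, derived
    phenotype computation (BMI, Friedewald LDL-c, vitamin D status
    classification, percent energy from macronutrients), normality-gated
    log transformation, covariate-adjusted association models, GRS-by-diet
    interaction models with dietary tertile stratification, and a seeded
    synthetic-cohort generator with planted effects for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
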