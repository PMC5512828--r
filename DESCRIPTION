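Package: penrisk
Title: Total Cardiovascular Risk Assessment and Treatment Concordance for
    Primary-Care NCD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of total cardiovascular risk based
    prevention in primary-care non-communicable disease programmes.
    Implements WHO/ISH risk chart scoring (cholesterol variant) as a banded
    table lookup, WHO PEN derived cohort inclusion and lipid-lowering
    treatment eligibility rules, index-date measurement selection with
    constant and regression-based imputation, prescribing concordance
    tables with binomial confidence intervals, documented-versus-calculated
    risk agreement analysis with Cohen's kappa, and a calibrated synthetic
    electronic-medical-record cohort generator so every pipeline stage is
    testable without access to clinic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
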