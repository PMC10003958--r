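Package: specimeq
Title: Specimen Equivalence and Method Comparison for Point-of-Care
    Creatinine and Blood Urea Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for verifying a point-of-care analyzer
    against reference chemistry analyzers and for judging whether
    alternative specimen types (serum, citrated whole blood) may stand in
    for the manufacturer-validated primary specimen (heparinized whole
    blood) when measuring creatinine and blood urea nitrogen.  Implements
    Passing-Bablok nonparametric regression with rank-based and bootstrap
    percentile confidence intervals, Bland-Altman agreement summaries,
    systematic differences at medical decision levels judged against
    total-allowable-error limits, duplicate-replicate imprecision,
    SD ratios with paired-bootstrap confidence intervals, and a CLSI
    EP35-style three-tier acceptance decision.  Includes a synthetic
    paired-duplicate cohort generator so every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
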