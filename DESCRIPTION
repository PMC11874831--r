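Package: comorbid
Title: Comorbidity Burden Estimation for Inpatient Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-step pipeline for estimating the comorbidity burden of
    inpatient cancer cohorts from admission-level hospital records: cohort
    inclusion/exclusion filtering, NCI Comorbidity Index scoring (Charlson
    weights with severity grading) from ICD-10 diagnosis lists, discovery of
    comorbidity patterns by agglomerative hierarchical clustering of condition
    indicators under a Pearson-correlation distance, and covariate-adjusted
    logistic and linear models relating each comorbidity cluster to treatment
    choice and medical cost. Includes a synthetic electronic-health-record
    cohort generator with planted condition co-occurrence blocks so the whole
    pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
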