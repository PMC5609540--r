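Package: endoxpred
Title: CYP2D6 Genotype-Based Prediction of Plasma Endoxifen in Tamoxifen
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers tamoxifen-to-endoxifen metabolic capacity from CYP2D6
    star-allele diplotypes. Implements allele functional classification and
    activity scoring (including a *10-downgraded scoring dialect), five
    diplotype-to-metabolizer-phenotype assignment schemes (Codeine, TAM1-TAM4),
    robust linear modelling of endoxifen endpoints with bootstrap
    variance-explained estimates, and ROC/Youden classification of patients
    above or below the 5.9 ng/mL clinical endoxifen threshold. A calibrated
    synthetic cohort generator emulating the statistical structure of a
    multi-ethnic tamoxifen pharmacokinetic study makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
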