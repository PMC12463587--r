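Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling of Switch
    Maintenance Therapy in Advanced Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable partitioned-survival cost-effectiveness pipeline for
    comparing ramucirumab plus paclitaxel switch maintenance against continued
    oxaliplatin-based chemotherapy in advanced HER2-negative gastric and
    gastro-oesophageal junction cancer, from the Chinese and United States
    payer perspectives. Covers pseudo individual-patient-data reconstruction
    from digitized Kaplan-Meier curves (Guyot algorithm), parametric survival
    extrapolation with AIC/BIC model selection, regimen- and body-size-based
    costing, a three-state partitioned survival cohort model with discounting,
    incremental cost-effectiveness ratios, one-way (tornado) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, price
    scenario analysis, and threshold-price search. Includes a synthetic trial
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
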