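Package: sahcue
Title: Pre-Trial Cost-Utility Modelling of Cerebral Infarction Reduction
    in Aneurysmal Subarachnoid Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic engine for pre-trial cost-utility assessment of
    therapeutic interventions that reduce the occurrence of cerebral infarction
    in aneurysmal subarachnoid hemorrhage (aSAH) patients. Simulates 100-patient
    cohorts stratified by cerebral-infarction status with a simple three-state
    (functionally independent / functionally dependent / dead) Markov model over
    30 years, accumulates acute, disability-related and nursing-home costs,
    computes point-in-time quality-adjusted life years (QALYs) at 1-, 5- and
    30-year horizons, derives incremental cost-utility ratios (ICERs) for
    interventions of given per-patient cost and infarction-reduction effect,
    classifies them against willingness-to-pay thresholds, costs drug dosing
    regimens, and runs one-way deterministic sensitivity (tornado) analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
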