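Package: fifascore
Title: Fitness-Tracker Assisted Frailty Assessment (FIFA Score)
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and evaluation of the FItness-tracker assisted
    Frailty-Assessment (FIFA) score from daily wearable activity summaries.
    Aggregates device-days into weekly patient profiles, derives per-category
    cutoffs by maximising the Youden index, assigns a 0-3 point score mapped
    to four frailty stages, and compares its discrimination of in-hospital
    mortality against the Edmonton Frail Scale classification and the
    6-minute-walk-test gait-speed category using rank-based ROC analysis
    with Hanley-McNeil confidence intervals. Includes a latent-frailty
    cohort simulator for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
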