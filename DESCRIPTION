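Package: periCog
Title: Reliable Change Index Classification of Perioperative Cognitive
    Outcomes with Covariate-Adjusted Association Models
Version: 1.0.0
Authors@R:
    person("periCog", "Developers", email = "pericog@example.org",
           role = c("aut", "cre"))
Description: Implements a control-group-referenced Reliable Change Index
    (RCI) pipeline for classifying preoperative cognitive impairment
    (preCI) and 3-month postoperative cognitive dysfunction (POCD) from a
    seven-parameter neuropsychological test battery, together with the
    covariate-adjusted logistic and linear association models, ROC/AUC and
    variance-inflation diagnostics, cohort flow accounting, and a
    synthetic longitudinal cohort generator with known ground truth so the
    whole analysis is testable without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
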