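Package: interviewsim
Title: Simulated Investigative Interview Training with a Child Avatar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training simulator for investigative interviews of child
    witnesses. Codes interviewer questions into the eleven-type taxonomy
    used in child forensic interview research with a hybrid classifier
    (character or word N-gram features fed to a gradient-boosted tree
    ensemble, wrapped in deterministic rules for greetings, repetition
    detection via Jaccard similarity, and suggestive-keyword overrides),
    and answers them with a probabilistic child-avatar memory model that
    rewards recommended open-ended questions with accurate case details
    and lets suggestive questioning create incorrect details. Includes
    interview session management with transcripts and outcome measures,
    automated feedback and modeling interventions, inter-rater agreement
    statistics (percent agreement, Cohen's kappa with confidence
    interval), and a synthetic labeled-corpus generator so the whole
    pipeline trains and tests without confidential interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xgboost,
    jsonlite,
    yaml,
    withr,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
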