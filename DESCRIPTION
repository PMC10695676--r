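Package: fsmpec
Title: Prediction, Explanation, and Control of Probabilistic Finite-State
    Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how agents predict, explain, and control
    probabilistic finite-state machines. Provides machine specification,
    validation and simulation (including the easy/hard reference chatbot
    machines); generation of two-alternative forced-choice test questions in
    prediction, explanation and control tasks with visible or hidden
    intermediate states; frequency-based mental-model estimation from
    interaction logs; normative (Bayesian) and alternative-neglect scoring
    with a regularized log-evidence measure; a one-parameter noisy choice
    model with maximum-likelihood sensitivity estimation and likelihood-ratio
    comparison of answer rules; synthetic-participant generators; and
    harnesses replicating four behavioral experiment designs at desk scale,
    including a Monte-Carlo power analysis of cross-task score correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
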