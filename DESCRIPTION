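Package: t2dbn
Title: Discrete Bayesian Networks for Progression from Prediabetes to Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, learning and interrogating discrete Bayesian
    networks in epidemiological risk-factor studies, centred on the progression
    from prediabetes to type 2 diabetes (T2D) in working adults. Provides
    hill-climbing structure learning under an AIC score with expert block
    constraints (blacklists), bootstrap model averaging with arc-strength
    thresholding, Bayesian conditional-probability-table estimation under a
    Dirichlet prior, exact inference by variable elimination, Markov-blanket
    risk ranking, stepwise evidence trajectories, and k-fold cross-validation
    with a log-likelihood loss. Ships a calibrated ground-truth network and a
    synthetic cohort generator so every stage of the pipeline can be exercised
    end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
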