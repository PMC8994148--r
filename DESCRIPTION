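Package: gbsbn
Title: Bayesian Network Risk Prediction for Post-Vaccination
    Guillain-Barre Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens vaccine adverse-event (AE) surveillance reports,
    learns a discrete Bayesian network over the outcome, demographics and
    the most prevalent AE terms by constrained tabu search with BIC
    scoring, reduces it to the Markov blanket of the outcome, fits
    conditional probability tables by maximum likelihood, predicts
    per-vaccinee Guillain-Barre syndrome (GBS) risk by exact inference,
    and evaluates the model by repeated stratified cross-validation and
    external validation. Includes a synthetic cohort generator emulating
    the structure of VAERS-like influenza-vaccine AE reports, so the whole
    pipeline is testable without access to the raw surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
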