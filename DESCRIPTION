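Package: perilang
Title: Predicting Prenatal Depression Symptoms from Sparse App-Entered Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for modelling Edinburgh Postnatal Depression
    Scale (EPDS) scores from sparse, patient-entered free text collected in a
    prenatal smartphone app. Implements temporal pairing of text entries with
    subsequent EPDS screens, four families of language features (lexicon
    sentiment fluctuation, LIWC-style theme-dictionary percentages, latent
    Dirichlet allocation topics with cross-validated topic-number selection,
    and max-pooled word embeddings), participant-grouped data splitting, and
    a cross-validated LASSO predicting averaged EPDS, evaluated by AUROC at
    the moderate-to-severe threshold. Ships a synthetic cohort generator with
    planted latent-severity effects for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
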