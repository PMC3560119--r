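Package: oscctrack
Title: Multimodal Relapse Prediction and Disease-Evolution Monitoring for
    Oral Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-support toolkit for post-remission relapse of oral
    squamous cell carcinoma (OSCC). Implements a baseline multimodal
    classification pipeline over clinical, imaging, tissue-genomic and
    blood-genomic feature tables (sparse-feature removal, mode/mean
    imputation, SMOTE class rebalancing, probe-level quality control,
    SAM-style permutation differential expression with fold-change
    filtering, CFS and wrapper feature selection, stratified
    cross-validation and leave-one-patient-out evaluation, weighted
    majority-vote fusion of per-source classifiers) and a temporal
    disease-evolution monitor (per-patient genetic signature tracking and
    a discrete dynamic Bayesian network with BDe/BIC structure scoring,
    greedy and simulated-annealing search, exact inference on the
    unrolled network and relapse forecasting). Ships a synthetic-cohort
    generator with known ground truth so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
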