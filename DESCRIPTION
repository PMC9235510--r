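Package: carcipred
Title: Carcinogenic Potency Prediction from Molecular Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts continuous carcinogenic potency (log-reciprocal TD50) of
    small molecules from structure. Combines a message-passing graph encoder
    with scaled-dot-product attention, molecular fingerprint features
    (circular, path and structural-key schemes), and a multilayer perceptron
    head trained by multi-round alternation between mutagenicity and
    carcinogenicity objectives. Includes TD50 label engineering (harmonic-mean
    aggregation, log-reciprocal transform, non-carcinogenic sentinel),
    leakage-free canonical-SMILES splitting, evaluation statistics (Pearson,
    MSE, ROC/PR AUC, bootstrap uncertainty, DeLong and cross-seed tests),
    Tanimoto-kernel maximum mean discrepancy between dataset partitions,
    counterfactual molecule generation with toxicophore enrichment analysis,
    and a synthetic benchmark generator with planted toxicophore-driven
    potency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
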