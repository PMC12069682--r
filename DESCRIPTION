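Package: molbalance
Title: Imbalance-Aware Bioactivity Classification with Generative SMILES
    Oversampling and Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds binary bioactivity classifiers (active/inactive) on
    imbalanced compound datasets. Curates raw bioactivity tables with dual
    activity cutoffs, fingerprints molecules (1,024-bit circular ECFP4-style),
    performs Bemis-Murcko scaffold splitting and stratified cross-validation,
    and corrects class imbalance either by transfer learning from a larger
    related-target dataset or by oversampling the minority class with a
    character-level LSTM SMILES generator followed by Butina clustering and
    centroid selection. Includes classical resampling comparators (ENN,
    SMOTE-ENN, KSMOTE), an evaluation harness (sensitivity, specificity, MCC,
    G-mean, ROC AUC) and the Friedman / Conover-Friedman model-comparison
    protocol, plus a seeded synthetic two-class SMILES data generator for
    end-to-end testing without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineR,
    e1071,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
SystemRequirements: OpenBabel (>= 3.0, the 'obabel' executable on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
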