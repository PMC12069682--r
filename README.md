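# molbalance

Binary bioactivity classifiers (active vs. inactive against a protein
target) trained on the imbalanced datasets that public dose-response
repositories actually provide — and two ways of fixing the imbalance:

1. **Transfer learning**: pre-train the same deep network on a large
   related-target dataset and copy the first hidden layer into the target
   model before fine-tuning.
2. **Generative oversampling**: train a character-level LSTM language model
   (CharRNN) on the minority-class SMILES, sample new molecules, filter and
   standardize them, cluster the survivors with Butina sphere-exclusion
   clustering, and add the cluster centroids to the minority class.

The package covers the full workflow: curation with dual activity cutoffs,
ECFP4-style 1,024-bit fingerprints, Bemis-Murcko scaffold splitting,
stratified cross-validation, a DNN plus naive Bayes / random forest /
XGBoost baselines, classical resamplers (ENN, SMOTE-ENN, KSMOTE) as
comparators, and a statistical comparison protocol. A grammar-based
synthetic SMILES generator makes every stage testable without any external
database.

## The model

Compounds with measured potency `v` (µM) are labeled

    active    if v ≤ 1 µM   (relation ∈ {=, <, ≤})
    inactive  if v ≥ 10 µM  (relation ∈ {=, >, ≥})
    excluded  otherwise

Classification uses hashed circular fingerprints (radius 2, folded to 1,024
bits) fed to a feed-forward network 1024 → 1000 → 500 → 1 (ReLU, sigmoid
output, dropout 0.25, Adam, early stopping). Performance under imbalance is
read from sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, the Matthews
correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

G-mean `√(sensitivity · specificity)`, and rank-based ROC AUC. Strategies
are compared across CV folds with Friedman's test and the Conover-Friedman
post-hoc; one model counts as better than another only when the pairwise
test is significant **and** the mean improves on all three of MCC, ROC AUC
and G-mean.

## Requirements and installation

Everything runs in R (≥ 4.0) with OpenBabel (`obabel`) on the PATH and the
declared R dependencies (ChemmineR, e1071, ranger, xgboost, jsonlite, yaml).

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "molbalance", load_package = "installed")'
```

## Worked example

```r
library(molbalance)

# a seeded synthetic two-class dataset: 400 actives, 50 inactives (8:1)
g <- generate_dataset(synthetic_spec(400, 50, seed = 1))
split <- remove_cross_split_duplicates(scaffold_split(g$dataset, 0.8))
fp_tr <- morgan_fingerprints(split$train$canonical_smiles)
fp_te <- morgan_fingerprints(split$test$canonical_smiles)

# unbalanced baseline
cfg <- dnn_config(hidden_widths = c(128, 64), max_epochs = 80, seed = 1)
base <- train_dnn(fp_tr, split$train$label, cfg)
p <- predict_proba(base, fp_te)
classification_metrics(split$test$label, predict_label(p), p)

# CharRNN oversampling of the inactives
corpus <- split$train$canonical_smiles[split$train$label == "inactive"]
gen <- train_generator(corpus, charrnn_config(n_layers = 1, hidden_size = 128,
                                              epochs = 300, batch_size = 5,
                                              learning_rate = 0.002,
                                              dropout_rate = 0, seed = 1))
raw <- sample_smiles(gen, 1500, seed = 1)
adds <- filter_generated(raw, corpus, exclude = c(split$train$canonical_smiles,
                                                  split$test$canonical_smiles))
cent <- cluster_compounds(morgan_fingerprints(adds$canonical_smiles))$centroids
aug <- augment_dataset(split$train, adds[cent, ], "inactive")
```

Or run the whole comparison in one call:

```r
res <- run_benchmark(seed = 1)
res$metrics
#>            strategy sensitivity specificity       mcc     gmean  accuracy   roc_auc
#> 1          baseline           1        0.52 0.6609085 0.7211103 0.8636364 0.9841270
#> 2 generator_augment           1        0.60 0.7195889 0.7745967 0.8863636 0.9873016
#> 3          transfer           1        0.72 0.8049845 0.8485281 0.9204545 0.9936508
res$generation
#> generation_report: 1449/1500 valid (96.6%), uniqueness 0.08, novelty 0.77,
#>   internal diversity 0.86, SNN-to-train 0.61
```

The baseline classifier keeps perfect sensitivity but misses half the test
inactives (specificity 0.52); adding the generator's 44 cluster centroids
to the inactive class lifts specificity to 0.60 and G-mean from 0.72 to
0.77 on the scaffold-split test set, and transfer from a larger related
dataset helps as well — the qualitative pattern expected for these
strategies, consistent across seeds.

## Command line

A thin CLI over the same functions lives at `inst/cli/molbalance.R`:

```sh
Rscript inst/cli/molbalance.R synth --n-active 400 --n-inactive 50 --seed 7 --out-dir data
Rscript inst/cli/molbalance.R curate --in raw.csv --active-cutoff 1 --inactive-cutoff 10 --out curated.csv
Rscript inst/cli/molbalance.R cutoff-scan --in raw.csv --inactive-cutoffs 2,4,6,8,10 --out scan.csv
Rscript inst/cli/molbalance.R benchmark --seed 1 --out bench.csv
```

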