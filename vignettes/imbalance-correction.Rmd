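---
title: "Correcting class imbalance in bioactivity classification with generative oversampling and transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting class imbalance in bioactivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Public dose-response bioactivity data (EC50, IC50, Ki) for a single protein
target is almost always imbalanced toward actives, because inactive
measurements are rarely deposited. A classifier trained on such data tends to
call everything active: cross-validation looks excellent while specificity on
chemically distinct test sets collapses. `molbalance` implements a complete
workflow for building binary active/inactive classifiers on such data and for
correcting the imbalance in two ways:

1. **Transfer learning** — pre-train the same network on a much larger
   related-target dataset (e.g. pan-GPCR bioactivities when the target is a
   GPCR) and copy the first hidden layer's parameters into the target network
   before fine-tuning.
2. **Generative oversampling** — train a character-level LSTM language model
   (CharRNN) on the minority-class SMILES, sample new molecules, standardize
   and filter them, cluster the survivors with Butina sphere-exclusion
   clustering, and add the cluster centroids (real sampled molecules, not
   vector averages) to the minority class.

Classical feature-space resamplers (ENN, SMOTE-ENN, KSMOTE) are included as
comparators, and an evaluation harness scores every strategy with the metrics
that matter under imbalance (sensitivity, specificity, MCC, G-mean, ROC AUC)
and compares strategies with the Friedman test plus the Conover-Friedman
post-hoc, declaring one model better than another only when all three of
MCC, ROC AUC and G-mean are individually significant and improved.

## Curation model

Raw records carry a measured value, a relation (`=`, `<`, `>`, `<=`, `>=`)
and a unit. After conversion to micromolar, a dual cutoff labels compounds:
at or below the active cutoff (default 1 µM) with relation in `{=, <, <=}`
they are active; at or above the inactive cutoff (default 10 µM) with
relation in `{=, >, >=}` they are inactive — censored "greater-than" records
beyond the inactive cutoff are informative inactives even without an absolute
measurement. Everything strictly between the cutoffs is excluded as
ambiguous. One judgment call is not dictated by common practice: a censored
"less-than" bound *above* the active cutoff proves nothing about either class,
so it is excluded (symmetric to the treatment of ">" bounds inside the band);
the curation log records how many records this touches.

Structures are standardized by parsing, desalting (largest organic fragment
by heavy-atom count, carbon-containing fragments preferred), neutralizing
formal charges where chemically sensible, and canonicalizing; the chemistry
itself is delegated to OpenBabel. Because the parser silently repairs certain
malformed strings (unbalanced open parentheses), a syntactic balance check
runs first so such strings are rejected with reason `parse_error` rather than
truncated. Within a class, duplicate canonical SMILES collapse to the first
occurrence (determinism under stable input order); a SMILES appearing under
both labels removes *both* records.

The dual-cutoff choice itself can be audited with `cutoff_scan()`: with the
active cutoff fixed, each candidate inactive cutoff relabels the data,
re-runs the full dedup, and counts actives whose maximum Tanimoto similarity
to any inactive exceeds 0.5. Because the inactive sets are nested, both the
inactive count and the overlap count are non-increasing in the cutoff; the
scan reports, the user chooses.

## Representation

Molecules are represented as hashed circular fingerprints in the ECFP4
convention (bond radius 2) folded to 1,024 presence bits. The underlying
extended-connectivity computation comes from OpenBabel at 4,096 bits and is
OR-folded to the configured width, preserving determinism and the
identical-molecule/identical-vector guarantee. Tanimoto similarity is
`|A∩B| / |A∪B|` on the on-bits, defined as 0 for two all-zero vectors (the
conservative choice: it cannot inflate overlap counts). Six physicochemical
descriptors (molecular weight, logP, rings, rotatable bonds, H-bond donors
and acceptors) support class-distribution profiling; the ring count is the
ring-closure count of the canonical SMILES, which equals the SSSR size.

## Splitting

Generalization to new chemotypes is stressed with a Bemis-Murcko scaffold
split: each molecule maps to the canonical SMILES of its framework (ring
systems plus linkers; side chains pruned; atoms attached through double or
triple bonds retained, so carbonyl oxygens stay). Acyclic molecules share
the reserved empty key and travel together. Scaffold groups are sorted by
descending size with lexicographic tie-breaks and assigned greedily to the
training side until the 80% target is reached — a deterministic procedure,
so tests can assert exact splits. The split is by compound count, not
scaffold count. A post-split hygiene step removes any training compound
whose fingerprint is identical to a test compound's.

Cross-validation folds are stratified: each class is permuted under the seed
and dealt round-robin, which bounds the per-fold class deviation at one
compound per class by construction.

## The classifier and the transfer mechanism

The reference classifier is a feed-forward network
1,024 → 1,000 → 500 → 1 (ReLU hidden layers, sigmoid output), binary
cross-entropy, Adam at learning rate 0.001, batch size 64, up to 2,000
epochs, dropout 0.25 at each hidden layer, early stopping with patience 50.
Early stopping monitors the *training* loss: no validation split is carved
out, which preserves the 80:20 design; the monitored quantity is
configurable. The decision threshold is fixed at 0.5 with ties labeled
active. Training, backpropagation and Adam are implemented directly on
base-R matrix operations, which keeps the transfer mechanism transparent:
`transfer_weights()` copies the chosen hidden layers' weights and biases
exactly from the source model into a freshly initialized target network and
returns the initialization; everything else (optimizer, loss,
hyperparameters) is untouched. The default transfers the first hidden layer
only and fine-tunes it rather than freezing — with no guidance otherwise,
fine-tuning is the less constrained choice, and both the layer list and the
behavior are explicit arguments. Naive Bayes (Bernoulli-style with Laplace
smoothing), random forest and gradient boosting baselines wrap e1071,
ranger and xgboost behind the same probability contract.

## The CharRNN generator

The generator is a stacked LSTM language model over a SMILES token
vocabulary: tokens are single characters except the two-character element
symbols `Cl` and `Br` (treating them as two tokens would make valid halogen
generation needlessly hard; bracket-atom internals and ring-closure digits
stay character-split, honoring the character-level design). BEGIN, END and
PAD specials are appended to the sorted corpus tokens, and tokenization is
lossless by construction. The production architecture is three LSTM layers
of hidden size 600 with dropout 0.2 between intermediate layers and a
softmax head, trained by teacher-forced next-token maximum likelihood with
Adam (learning rate 0.001, batch size 64, 50 epochs); padded positions are
masked out of the loss. Sampling starts at BEGIN and draws from the
temperature-scaled softmax (default temperature 1.0) until END or a length
cap; BEGIN and PAD are masked out of the sampling distribution.

Generated strings pass through four filters: standardization (parse
failures discarded), a length filter removing strings shorter in characters
than the shortest training compound, canonical deduplication, and a novelty
filter against the training corpus and, when supplied, the opposing class.
Generation quality is summarized MOSES-style: validity, uniqueness, novelty,
internal diversity (1 − mean pairwise Tanimoto) and mean
similarity-to-nearest-training-neighbor.

Survivors are clustered with Butina sphere-exclusion on Tanimoto distance
(default cutoff 0.6): compounds are ranked by neighbor count; each
unassigned compound with the most neighbors founds a cluster absorbing its
unassigned neighbors, ties breaking on input order. The founder — a real
generated molecule — is the centroid; averaging bit vectors would not yield
a molecule. When a fixed number of clusters is wanted, `cluster_to_count()`
bisects the cutoff. Centroids are appended to the minority class with
`source = "generated"` and the full dedup rules re-applied.

## What the synthetic generator emulates — and what it does not

Because the real public datasets cannot be bundled, every stage is exercised
by a grammar-based synthetic generator: six ring cores (benzene, pyridine,
pyrimidine, indole, piperidine, cyclohexane) decorated at enumerated
positions with 1–3 of 12 substituents, two of which carry rings (phenyl,
cyclopropyl) so each family spans many distinct Bemis-Murcko scaffolds.
Validity is guaranteed by construction, and uniqueness is enforced on
canonical forms. Labels correlate with scaffold family — half the families
are active-dominant — which mirrors the scaffold-activity clustering that
scaffold splits are designed to stress; `cross_family_mixing` (default 0.1)
moves a fraction of inactives into active-dominant families, dialing class
separability down. An optional screening-style test set is inversely
imbalanced at roughly 75 inactives per active. `generate_bioactivities()`
attaches seeded log-uniform values (actives 0.01–1 µM, inactives 10–100 µM,
one fifth of them censored ">" records, half of all rows restated in nM) so
curation and cutoff scanning run end-to-end.

Passing tests on this world shows the machinery is correct — labeling,
splitting, training, augmentation, statistics — not that the method will
improve any particular real target: synthetic families are cleaner than real
SAR landscapes, molecules are small and neutral, and no assay noise,
stereochemistry, tautomerism or activity cliffs are modeled.

## Numerical choices

* MCC is defined as 0 whenever a marginal is empty (constant predictor
  carries no correlation).
* ROC AUC uses the rank (Mann-Whitney) formulation with half credit for
  ties, and is reported missing — not 0 — for single-class truth, which is
  why all-active external sets are summarized by accuracy instead.
* The Friedman omnibus uses CV folds as blocks and models as treatments
  (average ranks on ties); the Conover-Friedman post-hoc refers pairwise
  rank-sum differences to a t distribution with (n−1)(k−1) degrees of
  freedom. No multiplicity adjustment is applied by default (none is part
  of the protocol); a step-down adjustment is available by argument.
* "Significantly better" requires pairwise p < 0.05 *and* a higher mean on
  every one of MCC, ROC AUC and G-mean simultaneously.
* Dropout uses inverted scaling so inference needs no rescaling; weight
  initialization is He-style for ReLU layers; the LSTM forget-gate bias
  starts at 1.
* All seeded operations save and restore the caller's RNG state, and the
  pipeline derives per-stage seeds from the global seed by a stable string
  hash so stages can be re-run independently.

## Benchmark problem sizes

The package's end-to-end benchmark (`run_benchmark()`) uses a 400:50
(8:1) synthetic dataset, a reduced classifier (128/64 hidden units, 80
epochs) and a reduced generator, chosen so a full
baseline-vs-augmented-vs-transfer comparison completes in minutes on one
CPU while preserving the qualitative behavior of the full-size
architecture: near-perfect sensitivity with depressed specificity at
baseline, and specificity recovery after minority-class augmentation. The
production architecture (1,000/500 hidden units; 3×600 LSTM) remains the
default for real datasets.

## Known limitations

* Charge neutralization relies on OpenBabel's `--neutralize` operation and
  does not cover every exotic protomer; stereochemistry is preserved but not
  corrected or enumerated.
* The Butina implementation materializes the full similarity matrix, which
  is appropriate up to tens of thousands of compounds, not millions.
* Transformer-based generation is out of scope; externally generated SMILES
  can be imported through the same filter/cluster/augment path
  (`filter_generated()` accepts any raw SMILES vector).
* The LSTM trains on CPU via base-R matrix algebra: ideal for the
  minority-class corpus sizes this workflow targets (hundreds of SMILES),
  not for multi-million-molecule pre-training.
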