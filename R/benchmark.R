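# End-to-end imbalance benchmark on the synthetic grammar: baseline DNN vs
# generator-augmented vs transfer-initialized training, evaluated on a
# scaffold-split test set. This is the package's desk-scale rehearsal of
# the full study design; model sizes are reduced relative to the production
# defaults so a benchmark run stays in the minutes range on one CPU.

#' Benchmark configuration defaults
#'
#' The benchmark dataset is 8:1 imbalanced (400 actives, 50 inactives)
#' with the default family mixing of 0.1; the classifier is a reduced DNN
#' (256/128 hidden units) and the generator a reduced CharRNN (2 x 128)
#' trained long enough to learn the grammar from a few dozen SMILES.
#'
#' @param n_active,n_inactive synthetic class sizes.
#' @param dnn_hidden hidden widths of the benchmark classifier.
#' @param dnn_epochs epoch cap for the benchmark classifier.
#' @param charrnn_layers,charrnn_hidden,charrnn_epochs reduced generator
#'   architecture.
#' @param n_generate raw SMILES sampled from the generator.
#' @param cluster_cutoff Butina Tanimoto-distance cutoff for centroid
#'   selection.
#' @export
benchmark_config <- function(n_active = 400L, n_inactive = 50L,
                             dnn_hidden = c(128L, 64L), dnn_epochs = 80L,
                             source_epochs = 40L,
                             charrnn_layers = 1L, charrnn_hidden = 128L,
                             charrnn_epochs = 300L, charrnn_batch = 5L,
                             n_generate = 1500L, cluster_cutoff = 0.6) {
  list(n_active = n_active, n_inactive = n_inactive,
       dnn_hidden = dnn_hidden, dnn_epochs = dnn_epochs,
       source_epochs = source_epochs,
       charrnn_layers = charrnn_layers, charrnn_hidden = charrnn_hidden,
       charrnn_epochs = charrnn_epochs, charrnn_batch = charrnn_batch,
       n_generate = n_generate, cluster_cutoff = cluster_cutoff)
}

#' Run the imbalance-correction benchmark for one seed
#'
#' Builds the seeded synthetic dataset, scaffold-splits it 80:20 (with
#' post-split fingerprint dedup), then trains and evaluates three
#' strategies on the held-out scaffold test set: an unbalanced baseline
#' DNN, a DNN trained after CharRNN oversampling of the minority class
#' (generated SMILES standardized, length-filtered, deduplicated, Butina
#' cluster centroids added as inactives), and a DNN fine-tuned from a
#' source model pre-trained on a larger related synthetic dataset.
#'
#' @param seed integer seed controlling the dataset and every model.
#' @param cfg a [benchmark_config()].
#' @param fp fingerprint configuration.
#' @return list with `metrics` (data.frame, one row per strategy),
#'   `generation` (the CharRNN `generation_report`), and counts.
#' @export
run_benchmark <- function(seed = 1L, cfg = benchmark_config(),
                          fp = fp_config()) {
  spec <- synthetic_spec(cfg$n_active, cfg$n_inactive, seed = seed)
  gen <- generate_dataset(spec)
  split <- scaffold_split(gen$dataset, 0.8)
  split <- remove_cross_split_duplicates(split, fp)
  train <- split$train; test <- split$test
  fp_tr <- morgan_fingerprints(train$canonical_smiles, fp)
  fp_te <- morgan_fingerprints(test$canonical_smiles, fp)

  dnn_cfg <- dnn_config(input_width = fp$n_bits, hidden_widths = cfg$dnn_hidden,
                        max_epochs = cfg$dnn_epochs, seed = seed)
  evaluate <- function(model, strategy) {
    pr <- predict_proba(model, fp_te)
    m <- classification_metrics(test$label, predict_label(pr), pr)
    cbind(data.frame(strategy = strategy, stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  }

  baseline <- train_dnn(fp_tr, train$label, dnn_cfg)
  out <- list(evaluate(baseline, "baseline"))

  # --- generator augmentation ---
  corpus <- train$canonical_smiles[train$label == "inactive"]
  gcfg <- charrnn_config(n_layers = cfg$charrnn_layers,
                         hidden_size = cfg$charrnn_hidden,
                         epochs = cfg$charrnn_epochs,
                         batch_size = min(cfg$charrnn_batch, length(corpus)),
                         learning_rate = 0.002, dropout_rate = 0,
                         seed = seed)
  generator <- train_generator(corpus, gcfg)
  raw <- sample_smiles(generator, cfg$n_generate, seed = seed)
  report <- generation_metrics(raw, corpus, fp)
  adds <- filter_generated(raw, corpus,
                           exclude = c(train$canonical_smiles,
                                       test$canonical_smiles))
  n_centroids <- 0L
  if (nrow(adds) > 1L) {
    gfp <- morgan_fingerprints(adds$canonical_smiles, fp)
    clus <- cluster_compounds(gfp, cfg$cluster_cutoff)
    adds <- adds[clus$centroids, , drop = FALSE]
    n_centroids <- nrow(adds)
  }
  aug <- augment_dataset(train, adds, "inactive")
  fp_aug <- morgan_fingerprints(aug$canonical_smiles, fp)
  augmented <- train_dnn(fp_aug, aug$label, dnn_cfg)
  out <- c(out, list(evaluate(augmented, "generator_augment")))

  # --- transfer from a larger related synthetic source ---
  src_spec <- synthetic_spec(as.integer(1.5 * cfg$n_active),
                             3L * cfg$n_inactive, seed = seed + 10000L)
  src <- generate_dataset(src_spec)$dataset
  # source must not leak target compounds
  src <- src[!src$canonical_smiles %in%
               c(train$canonical_smiles, test$canonical_smiles), , drop = FALSE]
  fp_src <- morgan_fingerprints(src$canonical_smiles, fp)
  src_cfg <- dnn_cfg
  src_cfg$seed <- seed + 10000L
  src_cfg$max_epochs <- cfg$source_epochs
  source_model <- pretrain_source(fp_src, src$label, src_cfg)
  init <- transfer_weights(source_model, dnn_cfg, layers_to_transfer = 1L)
  transferred <- train_dnn(fp_tr, train$label, dnn_cfg, init = init)
  out <- c(out, list(evaluate(transferred, "transfer")))

  list(metrics = do.call(rbind, out), generation = report,
       n_train = nrow(train), n_test = nrow(test),
       n_generated_kept = nrow(adds), n_centroids = n_centroids)
}
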