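test_that("vocabulary tokenizes losslessly with atomic halogens", {
  vocab <- build_vocabulary(c("CCO", "CCl", "BrCC(=O)N"))
  expect_setequal(setdiff(vocab$tokens,
                          c("<bos>", "<eos>", "<pad>")),
                  c("C", "O", "Cl", "Br", "(", ")", "=", "N"))
  # Cl is one token, not two
  expect_length(tokenize(vocab, "CCl"), 2)
  # round trip for every corpus string and some recombinations
  for (s in c("CCO", "CCl", "BrCC(=O)N", "ClCCBr", "N(C)(C)C=O")) {
    expect_identical(detokenize(vocab, tokenize(vocab, s)), s)
  }
  expect_error(tokenize(vocab, "CCS"), "outside the vocabulary")
})

test_that("vocabulary round-trip holds over synthetic corpora", {
  g <- generate_dataset(synthetic_spec(30, 10, seed = 8))
  corpus <- g$dataset$canonical_smiles
  vocab <- build_vocabulary(corpus)
  for (s in corpus) {
    expect_identical(detokenize(vocab, tokenize(vocab, s)), s)
  }
})

small_model <- function(corpus, epochs = 250, seed = 7, hidden = 32L) {
  train_generator(corpus, charrnn_config(
    n_layers = 1L, hidden_size = hidden, dropout_rate = 0,
    epochs = epochs, batch_size = length(corpus), seed = seed,
    max_sample_length = 40L))
}

test_that("training reduces the next-token loss", {
  corpus <- c("CCO", "CCN", "CCCC", "CC(C)O", "c1ccccc1")
  m <- small_model(corpus, epochs = 60)
  expect_lt(tail(m$history, 1), m$history[1])
  expect_length(m$history, 60)
})

test_that("an overfit generator memorizes and decodes a training string", {
  corpus <- c("CCO", "CCN", "c1ccccc1", "CC(C)O", "CCCC")
  m <- small_model(corpus, epochs = 300)
  greedy <- sample_smiles(m, 1, greedy = TRUE)
  expect_true(greedy %in% corpus)
  # deterministic under seed
  m2 <- small_model(corpus, epochs = 300)
  expect_equal(tail(m$history, 1), tail(m2$history, 1))
})

test_that("sampling respects the vocabulary, seed and temperature limit", {
  corpus <- c("CCO", "CCN", "CCCC")
  m <- small_model(corpus, epochs = 150)
  expect_identical(sample_smiles(m, 0), character(0))
  s <- sample_smiles(m, 30, seed = 4)
  vocab_chars <- setdiff(m$vocabulary$tokens, c("<bos>", "<eos>", "<pad>"))
  for (x in s) {
    toks <- unlist(strsplit(gsub("Cl|Br", "", x), ""))
    expect_true(all(toks %in% vocab_chars))
  }
  # reproducible stream
  expect_identical(s, sample_smiles(m, 30, seed = 4))
  # temperature -> 0 converges to the greedy argmax rollout
  expect_identical(sample_smiles(m, 3, seed = 1, temperature = 1e-6),
                   sample_smiles(m, 3, seed = 1, greedy = TRUE))
})

test_that("next-token outputs are probability distributions", {
  corpus <- c("CCO", "CCN")
  m <- small_model(corpus, epochs = 30, hidden = 16L)
  for (prefix in list(integer(0), tokenize(m$vocabulary, "C"),
                      tokenize(m$vocabulary, "CC"))) {
    p <- next_token_distribution(m, prefix)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    # specials other than EOS are masked out
    expect_equal(unname(p["<bos>"] + p["<pad>"]), 0)
  }
})

test_that("the generated-SMILES filter applies all four stages", {
  corpus <- c("CCCCO", "CCCCN")  # min length 5
  raw <- c("C(((",        # invalid
           "xx",          # invalid
           "CCO",         # too short (3 < 5)
           "CCCCO",       # in training corpus
           "CCCCCN",      # keeper
           "NCCCCC",      # duplicate of keeper after canonicalization
           "CCCCCO")      # keeper
  out <- filter_generated(raw, corpus)
  expect_equal(nrow(out), 2)
  log <- attr(out, "log")
  expect_equal(log$n_raw, 7)
  expect_equal(log$n_valid, 5)
  expect_equal(log$n_long_enough, 4)
  expect_equal(log$n_unique, 3)
  expect_equal(log$n_novel, 2)
  expect_true(all(out$source == "generated"))
  # exclusion list removes opposing-class collisions
  out2 <- filter_generated(raw, corpus, exclude = out$canonical_smiles[1])
  expect_equal(nrow(out2), 1)
})

test_that("generation metrics match forced and brute-force values", {
  corpus <- c("CCO", "CCN", "CCCC")
  # generated == training corpus: novelty 0, snn 1, uniqueness 1
  rep1 <- generation_metrics(corpus, corpus)
  expect_equal(rep1$validity, 1)
  expect_equal(rep1$uniqueness, 1)
  expect_equal(rep1$novelty, 0)
  expect_equal(rep1$snn_to_train, 1)
  # all-distinct valid outputs: uniqueness 1
  rep2 <- generation_metrics(c("CCCO", "CCCCN"), corpus)
  expect_equal(rep2$uniqueness, 1)
  expect_equal(rep2$novelty, 1)
  # internal diversity equals the brute-force pairwise mean
  gen <- c("CCO", "CCCO", "c1ccccc1", "CCN")
  fps <- morgan_fingerprints(gen)
  sims <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    sims <- c(sims, tanimoto(fps$bits[i, ], fps$bits[j, ]))
  }
  rep3 <- generation_metrics(gen, corpus)
  expect_equal(rep3$internal_diversity, 1 - mean(sims), tolerance = 1e-12)
  # empty generation warns and zeroes the ratios
  expect_warning(rep4 <- generation_metrics(character(0), corpus))
  expect_equal(rep4$validity, 0)
})
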