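make_separable <- function(n = 40, n_bits = 64, seed = 2) {
  set.seed(seed)
  bits <- matrix(runif(n * n_bits) < 0.25, n, n_bits)
  bits[seq_len(n / 2), 1:8] <- TRUE
  bits[(n / 2 + 1):n, 1:8] <- FALSE
  fps <- structure(list(ids = paste0("c", 1:n), bits = bits,
                        config = fp_config(n_bits, 2L)),
                   class = "fingerprint_matrix")
  list(fps = fps, labels = rep(c("active", "inactive"), each = n / 2))
}

test_that("the DNN fits a linearly separable fingerprint set", {
  d <- make_separable()
  m <- train_dnn(d$fps, d$labels, test_dnn_config(seed = 3))
  p <- predict_proba(m, d$fps)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean(predict_label(p) == d$labels), 1.0)
  # training loss decreased
  expect_lt(tail(m$history, 1), m$history[1])
})

test_that("label-shuffled data gives chance-level held-out AUC", {
  set.seed(9)
  d <- make_separable(n = 80)
  labels <- sample(d$labels)  # destroy the signal
  tr <- 1:60; te <- 61:80
  sub <- function(fps, idx) structure(list(ids = fps$ids[idx],
                                           bits = fps$bits[idx, , drop = FALSE],
                                           config = fps$config),
                                      class = "fingerprint_matrix")
  m <- train_dnn(sub(d$fps, tr), labels[tr], test_dnn_config(seed = 1))
  auc <- roc_auc(predict_proba(m, sub(d$fps, te)), labels[te])
  expect_gt(auc, 0.25)
  expect_lt(auc, 0.75)
})

test_that("an untrained network still emits probabilities in (0,1)", {
  d <- make_separable()
  m <- train_dnn(d$fps, d$labels, test_dnn_config(max_epochs = 0L, seed = 1))
  p <- predict_proba(m, d$fps)
  expect_true(all(p > 0 & p < 1))
  # tie-break at the threshold labels active
  expect_identical(predict_label(0.5), "active")
})

test_that("single-class training data is rejected", {
  d <- make_separable()
  expect_error(train_dnn(d$fps, rep("active", 40), test_dnn_config()),
               "per class")
})

test_that("prediction rejects mismatched fingerprint configurations", {
  d <- make_separable()
  m <- train_dnn(d$fps, d$labels, test_dnn_config(max_epochs = 5L, seed = 1))
  other <- d$fps; other$config <- fp_config(128L, 2L)
  other$bits <- cbind(other$bits, other$bits)
  expect_error(predict_proba(m, other), "configuration")
})

test_that("naive Bayes posteriors match the hand-computed Bayes rule", {
  # 4 compounds, 3 bits; Laplace-smoothed Bernoulli per feature
  bits <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  fps <- structure(list(ids = paste0("c", 1:4), bits = bits > 0,
                        config = fp_config(64, 2)), class = "fingerprint_matrix")
  fps$config <- fp_config(64, 2); fps$config$n_bits <- 3L  # 3-bit toy width
  labels <- c("active", "active", "inactive", "inactive")
  m <- train_baseline("naive_bayes", fps, labels, seed = 1)
  p <- predict_proba(m, fps)
  # hand computation: P(b|y) = (count + 1) / (n_y + 2), priors 1/2
  lik <- function(x, rows) {
    prod(vapply(1:3, function(j) {
      th <- (sum(bits[rows, j]) + 1) / (length(rows) + 2)
      if (x[j] == 1) th else 1 - th
    }, numeric(1)))
  }
  for (i in 1:4) {
    pa <- lik(bits[i, ], 1:2); pi_ <- lik(bits[i, ], 3:4)
    expect_equal(p[i], pa / (pa + pi_), tolerance = 1e-9)
  }
})

test_that("a depth-1 single-tree forest yields piecewise-constant scores", {
  d <- make_separable()
  m <- train_baseline("random_forest", d$fps, d$labels, seed = 1,
                      num.trees = 1, max.depth = 1)
  p <- predict_proba(m, d$fps)
  expect_lte(length(unique(round(p, 10))), 2)
})

test_that("all baseline kinds train and predict on one fixture", {
  d <- make_separable()
  for (kind in c("naive_bayes", "random_forest", "gradient_boosting")) {
    m <- train_baseline(kind, d$fps, d$labels, seed = 7)
    p <- predict_proba(m, d$fps)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    # determinism under the seed
    m2 <- train_baseline(kind, d$fps, d$labels, seed = 7)
    expect_equal(p, predict_proba(m2, d$fps), info = kind)
  }
  expect_error(train_baseline("svm", d$fps, d$labels), "arg")
})

test_that("transferred layers reproduce source activations bit-for-bit", {
  d <- make_separable()
  cfg <- test_dnn_config(max_epochs = 30L, seed = 5)
  src <- pretrain_source(d$fps, d$labels, cfg)
  tcfg <- test_dnn_config(seed = 99)
  set.seed(31)
  X <- matrix(runif(10 * 64) < 0.3, 10, 64) * 1

  init1 <- transfer_weights(src, tcfg, layers_to_transfer = 1L)
  expect_identical(init1[[1]], src$layers[[1]])
  h_src <- pmax(sweep(X %*% src$layers[[1]]$W, 2, src$layers[[1]]$b, "+"), 0)
  h_tgt <- pmax(sweep(X %*% init1[[1]]$W, 2, init1[[1]]$b, "+"), 0)
  expect_identical(h_src, h_tgt)

  # transferring both hidden layers matches the source through layer 2
  init2 <- transfer_weights(src, tcfg, layers_to_transfer = c(1L, 2L))
  h2_src <- pmax(sweep(h_src %*% src$layers[[2]]$W, 2, src$layers[[2]]$b, "+"), 0)
  h2_tgt <- pmax(sweep(h_tgt %*% init2[[2]]$W, 2, init2[[2]]$b, "+"), 0)
  expect_identical(h2_src, h2_tgt)

  # non-transferred layers are freshly initialized (differ from source)
  expect_false(identical(init1[[2]]$W, src$layers[[2]]$W))
  # width mismatch is caught
  bad_cfg <- dnn_config(input_width = 64, hidden_widths = c(7L, 12L))
  expect_error(transfer_weights(src, bad_cfg, 1L), "mismatch")
})

test_that("self-transfer then fine-tuning does not break the model", {
  d <- make_separable()
  cfg <- test_dnn_config(seed = 5)
  base <- train_dnn(d$fps, d$labels, cfg)
  init <- transfer_weights(base, cfg, 1L)
  tuned <- train_dnn(d$fps, d$labels, cfg, init = init)
  p <- predict_proba(tuned, d$fps)
  m_base <- classification_metrics(d$labels, predict_label(predict_proba(base, d$fps)))
  m_tuned <- classification_metrics(d$labels, predict_label(p))
  expect_gte(m_tuned[["gmean"]], m_base[["gmean"]] - 0.05)
})

test_that("models survive a serialization round-trip", {
  d <- make_separable()
  m <- train_dnn(d$fps, d$labels, test_dnn_config(max_epochs = 20L, seed = 2))
  dir <- tempfile()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_model(dir)
  expect_identical(predict_proba(m, d$fps), predict_proba(m2, d$fps))
  unlink(dir, recursive = TRUE)
})
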