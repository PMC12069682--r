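# fixed 4-model x 10-fold fixture with one dominant model (model D);
# reference values computed with an independent rank/t-distribution
# implementation (NumPy/SciPy)
fixture_4x10 <- function() {
  m <- rbind(
    A = c(0.538414, 0.380246, 0.467915, 0.423453, 0.455187, 0.565145,
          0.61531, 0.442115, 0.557715, 0.584734),
    B = c(0.502321, 0.437323, 0.484905, 0.46941, 0.460277, 0.569499,
          0.620307, 0.486795, 0.581803, 0.588081),
    C = c(0.509235, 0.36616, 0.448597, 0.373433, 0.407778, 0.545707,
          0.581867, 0.470548, 0.563817, 0.552148),
    D = c(0.693752, 0.548148, 0.608371, 0.58531, 0.578444, 0.706028,
          0.734055, 0.601387, 0.73685, 0.720797))
  m
}

test_that("confusion counts match hand tallies", {
  truth <- rep(c("active", "inactive"), each = 5)
  pred <- c("active", "active", "active", "inactive", "inactive",
            "active", "inactive", "inactive", "inactive", "inactive")
  cc <- confusion(truth, pred)
  expect_equal(cc$tp, 3); expect_equal(cc$fn, 2)
  expect_equal(cc$fp, 1); expect_equal(cc$tn, 4)
  # perfect and all-active edge cases
  perf <- confusion(truth, truth)
  expect_equal(perf$fp + perf$fn, 0)
  alla <- confusion(truth, rep("active", 10))
  expect_equal(alla$fn + alla$tn, 0)
  expect_error(confusion(truth, pred[1:3]), "mismatch")
})

test_that("the hand-worked confusion case yields the printed metrics", {
  truth <- rep(c("active", "inactive"), each = 5)
  pred <- c("active", "active", "active", "inactive", "inactive",
            "active", "inactive", "inactive", "inactive", "inactive")
  m <- classification_metrics(truth, pred)
  expect_equal(m[["sensitivity"]], 0.6)
  expect_equal(m[["specificity"]], 0.8)
  expect_equal(m[["mcc"]], 10 / sqrt(600))
  expect_equal(m[["gmean"]], sqrt(0.48))
  expect_equal(m[["accuracy"]], 0.7)
})

test_that("metric conventions cover degenerate inputs", {
  truth <- rep(c("active", "inactive"), each = 3)
  m <- classification_metrics(truth, truth)
  expect_equal(unname(m[c("sensitivity", "specificity", "gmean", "mcc")]),
               c(1, 1, 1, 1))
  # constant predictor: MCC defined as 0
  m2 <- classification_metrics(truth, rep("active", 6))
  expect_equal(m2[["mcc"]], 0)
  # single-class truth: accuracy defined, AUC missing
  m3 <- classification_metrics(rep("active", 4), rep("active", 4),
                               scores = c(0.9, 0.8, 0.9, 0.7))
  expect_equal(m3[["accuracy"]], 1)
  expect_true(is.na(m3[["roc_auc"]]))
})

test_that("metrics agree with naive loop oracles on random vectors", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    truth <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("active", "inactive")
    scores <- round(runif(n), 2)  # rounding forces score ties
    pred <- predict_label(scores)
    m <- classification_metrics(truth, pred, scores)
    o <- naive_metrics(truth, pred)
    for (nm in names(o)) expect_identical(m[[nm]], o[[nm]])
    expect_lt(abs(m[["roc_auc"]] - naive_auc(scores, truth)), 1e-9)
    # structural facts
    expect_lte(m[["gmean"]], max(m[["sensitivity"]], m[["specificity"]]) + 1e-12)
  }
})

test_that("ROC AUC matches an established implementation", {
  set.seed(5)
  truth <- sample(c("active", "inactive"), 50, replace = TRUE)
  scores <- runif(50)
  ours <- roc_auc(scores, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Friedman test matches the reference on the fixed fixture", {
  m <- fixture_4x10()
  ft <- friedman_test(m)
  expect_lt(abs(ft$statistic - 24.84), 1e-9)
  expect_lt(abs(ft$p_value - 1.667673361339948e-05), 1e-12)
  # identical columns: statistic 0, p 1
  same <- matrix(rep(c(0.5, 0.5, 0.5), 10), 3, 10,
                 dimnames = list(c("A", "B", "C"), NULL))
  ft0 <- friedman_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  # row-order permutation leaves p unchanged
  ft_perm <- friedman_test(m[c(3, 1, 4, 2), ])
  expect_equal(ft$p_value, ft_perm$p_value)
  expect_error(friedman_test(m[1:2, ]), "at least 3")
})

test_that("Conover-Friedman p values match the independent reference", {
  m <- fixture_4x10()
  p <- conover_posthoc(m)
  ref <- rbind(
    c(1,              1.378585481113e-03, 2.478917321106e-02, 6.266096601820e-09),
    c(1.378585481113e-03, 1,              2.458576936592e-06, 5.892875648716e-05),
    c(2.478917321106e-02, 2.458576936592e-06, 1,              3.278057636338e-11),
    c(5.892875648716e-05 * 0 + 6.266096601820e-09, 5.892875648716e-05,
      3.278057636338e-11, 1))
  expect_true(all(abs(p - ref) < 1e-9))
  # symmetry with unit diagonal
  expect_identical(p, t(p))
  expect_equal(unname(diag(p)), rep(1, 4))
  # the dominant model's pairwise p values are the matrix minima
  off <- p; diag(off) <- NA
  expect_true(all(which(off == min(off, na.rm = TRUE), arr.ind = TRUE) %in%
                    c(3, 4)))
  # identical columns: everything 1
  same <- matrix(0.7, 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  expect_true(all(conover_posthoc(same) == 1))
})

test_that("the all-three-metrics rule fires only for a dominant model", {
  m <- fixture_4x10()
  tables <- list(mcc = m, roc_auc = m + 0.001, gmean = m * 0.9)
  verdict <- declare_better(tables)
  # D dominates everyone; nobody dominates D
  expect_true(all(verdict["D", c("A", "B", "C")]))
  expect_false(any(verdict[c("A", "B", "C"), "D"]))
  # significance on only part of the metrics blocks the verdict
  flat <- matrix(0.5, 4, 10, dimnames = list(rownames(m), NULL))
  verdict2 <- declare_better(list(mcc = m, roc_auc = flat, gmean = m))
  expect_false(any(verdict2))
  # all p = 1 -> no verdicts
  verdict3 <- declare_better(list(mcc = flat, roc_auc = flat, gmean = flat))
  expect_false(any(verdict3))
})

test_that("cross-validation produces a complete grid and sane nulls", {
  set.seed(21)
  n <- 60
  bits <- matrix(runif(n * 32) < 0.3, n, 32)
  labels <- sample(rep(c("active", "inactive"), c(40, 20)))  # no signal
  ds <- labeled_dataset(sprintf("s%d", 1:n), labels)
  fpcfg <- fp_config(64, 2)
  # patch width: embed 32 informative columns in a 64-bit frame
  bits <- cbind(bits, matrix(FALSE, n, 32))
  fake_fp <- structure(list(ids = ds$canonical_smiles, bits = bits,
                            config = fpcfg), class = "fingerprint_matrix")
  # use the harness through a baseline model on raw fingerprints
  folds <- stratified_kfold(ds, k = 5, seed = 2)
  rows <- list()
  for (f in 1:5) {
    tr <- folds$fold_of != f
    sub <- function(i) structure(list(ids = fake_fp$ids[i],
                                      bits = fake_fp$bits[i, , drop = FALSE],
                                      config = fpcfg),
                                 class = "fingerprint_matrix")
    mdl <- train_baseline("gradient_boosting", sub(tr), labels[tr],
                          seed = 3, nrounds = 20)
    pr <- predict_proba(mdl, sub(!tr))
    rows[[f]] <- classification_metrics(labels[!tr], predict_label(pr), pr)
  }
  aucs <- vapply(rows, `[[`, numeric(1), "roc_auc")
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("metric_table reshapes a report into complete matrices", {
  report <- expand.grid(model = "dnn", strategy = c("none", "transfer"),
                        fold = 1:3, surface = "cv",
                        stringsAsFactors = FALSE)
  report$mcc <- seq_len(nrow(report)) / 10
  tab <- metric_table(report, "mcc")
  expect_equal(dim(tab), c(2, 3))
  expect_false(anyNA(tab))
  expect_equal(tab["dnn+none", "fold2"],
               report$mcc[report$strategy == "none" & report$fold == 2])
})
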