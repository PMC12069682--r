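# Metrics, cross-validation harness and the statistical model-comparison
# protocol (Friedman omnibus + Conover-Friedman pairwise post-hoc, with the
# all-three-metrics significance rule).

#' Confusion counts
#'
#' @param y_true,y_pred character vectors in `{"active","inactive"}`;
#'   actives are the positive class.
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  structure(list(
    tp = sum(y_true == "active" & y_pred == "active"),
    tn = sum(y_true == "inactive" & y_pred == "inactive"),
    fp = sum(y_true == "inactive" & y_pred == "active"),
    fn = sum(y_true == "active" & y_pred == "inactive")
  ), class = "confusion_counts")
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' Ties in scores receive half credit; when only one class is present the
#' AUC is undefined and `NA` is returned.
#'
#' @param scores numeric scores (higher = more likely active).
#' @param y_true labels in `{"active","inactive"}`.
#' @return AUC in \[0, 1\] or `NA`.
#' @export
roc_auc <- function(scores, y_true) {
  pos <- y_true == "active"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric set
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, MCC (0 when any
#' marginal is empty), G-mean `sqrt(sens * spec)`, accuracy, and ROC AUC
#' from `scores` when provided (NA when truth is single-class).
#'
#' @param y_true,y_pred labels in `{"active","inactive"}`.
#' @param scores optional probabilities for the AUC.
#' @return named numeric vector with elements `sensitivity`, `specificity`,
#'   `mcc`, `gmean`, `accuracy`, `roc_auc`.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  cc <- confusion(y_true, y_pred)
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  gmean <- if (!is.na(sens) && !is.na(spec)) sqrt(sens * spec) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  auc <- if (!is.null(scores)) roc_auc(scores, y_true) else NA_real_
  c(sensitivity = sens, specificity = spec, mcc = mcc, gmean = gmean,
    accuracy = acc, roc_auc = auc)
}

#' Friedman omnibus test over a model-by-fold metric table
#'
#' Blocks are CV folds, treatments are models; within-fold ranking uses
#' average ranks on ties and the chi-square approximation.
#'
#' @param metric_table numeric matrix, rows = models (rownames required),
#'   columns = folds; complete (no NA).
#' @return list with `statistic` and `p_value`.
#' @export
friedman_test <- function(metric_table) {
  if (anyNA(metric_table)) stop("metric table must be complete")
  if (nrow(metric_table) < 3 || ncol(metric_table) < 2) {
    stop("need at least 3 models and 2 folds")
  }
  ft <- stats::friedman.test(t(metric_table))
  stat <- unname(ft$statistic); p <- unname(ft$p.value)
  if (is.nan(stat)) {
    # every fold fully tied: no evidence of any difference
    stat <- 0; p <- 1
  }
  list(statistic = stat, p_value = p)
}

#' Conover-Friedman all-pairs post-hoc test
#'
#' Pairwise comparisons on the Friedman within-block ranks (Conover 1999):
#' for rank sums `R_i`, `t = (R_i - R_j) / sqrt(2 n (A - B) / ((n-1)(k-1)))`
#' with `A` the sum of squared ranks and `B = sum(R_j^2)/n`, referred to a
#' t distribution with `(n-1)(k-1)` degrees of freedom (two-sided). No
#' multiplicity adjustment is applied unless requested.
#'
#' @param metric_table numeric matrix, rows = models, columns = folds.
#' @param p_adjust_method a method of [stats::p.adjust()] (default
#'   `"none"`).
#' @return symmetric matrix of p values with unit diagonal.
#' @export
conover_posthoc <- function(metric_table, p_adjust_method = "none") {
  if (anyNA(metric_table)) stop("metric table must be complete")
  k <- nrow(metric_table); n <- ncol(metric_table)
  if (k < 3 || n < 2) stop("need at least 3 models and 2 folds")
  ranks <- apply(metric_table, 2, rank)        # k x n, ranks within folds
  Rsum <- rowSums(ranks)
  A <- sum(ranks^2)
  B <- sum(Rsum^2) / n
  df <- (n - 1) * (k - 1)
  denom2 <- 2 * n * (A - B) / df
  p <- matrix(1, k, k, dimnames = list(rownames(metric_table),
                                       rownames(metric_table)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (denom2 <= 0) { pij <- 1 }  # all models identical in every fold
      else {
        tstat <- (Rsum[i] - Rsum[j]) / sqrt(denom2)
        pij <- 2 * stats::pt(-abs(tstat), df)
      }
      p[i, j] <- p[j, i] <- min(1, pij)
    }
  }
  if (p_adjust_method != "none") {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = p_adjust_method)
    p[up] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Pairwise "significantly better" verdicts across three metrics
#'
#' Model A is declared significantly better than model B only when the
#' Conover-Friedman pairwise p value is below `alpha` for every one of the
#' supplied metrics AND A's mean exceeds B's on every one of them.
#'
#' @param metric_tables named list of model-by-fold matrices (canonically
#'   `mcc`, `roc_auc`, `gmean`), identical model sets.
#' @param alpha significance level.
#' @return logical matrix `better[A, B]`.
#' @export
declare_better <- function(metric_tables, alpha = 0.05) {
  stopifnot(length(metric_tables) >= 1)
  models <- rownames(metric_tables[[1]])
  k <- length(models)
  better <- matrix(TRUE, k, k, dimnames = list(models, models))
  for (tab in metric_tables) {
    stopifnot(identical(rownames(tab), models))
    p <- conover_posthoc(tab)
    means <- rowMeans(tab)
    better <- better & (p < alpha) & outer(means, means, ">")
  }
  diag(better) <- FALSE
  better
}

# --- cross-validation harness -----------------------------------------------

train_by_spec <- function(pipeline_spec, fps, labels, seed) {
  kind <- pipeline_spec$model
  if (kind == "dnn") {
    cfg <- pipeline_spec$dnn_cfg
    if (is.null(cfg)) cfg <- dnn_config(input_width = fps$config$n_bits)
    cfg$seed <- seed
    init <- NULL
    if (identical(pipeline_spec$strategy, "transfer")) {
      if (is.null(pipeline_spec$source_model)) {
        stop("transfer strategy requires a pre-trained source model")
      }
      layers <- pipeline_spec$layers_to_transfer
      if (is.null(layers)) layers <- 1L
      init <- transfer_weights(pipeline_spec$source_model, cfg, layers)
    }
    train_dnn(fps, labels, cfg, init = init)
  } else {
    train_baseline(kind, fps, labels, seed = seed)
  }
}

#' Cross-validate a modeling pipeline
#'
#' For every fold: the balancing strategy is applied to the training portion
#' only (augmentation/resampling re-derived inside the fold, never touching
#' held-out compounds), the model is trained, and the held-out fold plus
#' every external test set are scored. A leakage guard asserts that no
#' augmented compound's canonical SMILES occurs in the held-out fold.
#'
#' @param ds training `labeled_dataset`.
#' @param folds a `fold_plan` for `ds`.
#' @param pipeline_spec list naming `model` (`"dnn"`, `"naive_bayes"`,
#'   `"random_forest"`, `"gradient_boosting"`) and `strategy` (`"none"`,
#'   `"transfer"`, `"generator_augment"`, `"enn"`, `"smote_enn"`,
#'   `"ksmote"`), plus strategy inputs: `dnn_cfg`, `source_model`,
#'   `layers_to_transfer`, `charrnn_cfg`, `n_generate`,
#'   `cluster_cutoff`.
#' @param external_tests named list of `labeled_dataset` test sets scored at
#'   every iteration.
#' @param config fingerprint configuration.
#' @return long-format data.frame: `model`, `strategy`, `fold`, `surface`,
#'   and one column per metric.
#' @export
cross_validate <- function(ds, folds, pipeline_spec,
                           external_tests = list(), config = fp_config()) {
  strategy <- pipeline_spec$strategy
  if (is.null(strategy)) strategy <- "none"
  all_fp <- morgan_fingerprints(ds$canonical_smiles, config)
  ext_fp <- lapply(external_tests, function(tst) {
    morgan_fingerprints(tst$canonical_smiles, config)
  })
  rows <- list()
  for (f in seq_len(folds$k)) {
    tr_idx <- which(folds$fold_of != f)
    te_idx <- which(folds$fold_of == f)
    tr_bits <- all_fp$bits[tr_idx, , drop = FALSE]
    tr_lab <- ds$label[tr_idx]
    tr_smi <- ds$canonical_smiles[tr_idx]
    held_out <- ds$canonical_smiles[te_idx]
    seed_f <- folds$seed * 1000L + f

    if (strategy == "generator_augment") {
      minority <- names(which.min(table(tr_lab)))
      corpus <- tr_smi[tr_lab == minority]
      gcfg <- pipeline_spec$charrnn_cfg
      if (is.null(gcfg)) gcfg <- charrnn_config()
      gcfg$seed <- seed_f
      gen <- train_generator(corpus, gcfg)
      n_gen <- if (is.null(pipeline_spec$n_generate)) 1000L else pipeline_spec$n_generate
      raw <- sample_smiles(gen, n_gen, seed = seed_f)
      adds <- filter_generated(raw, corpus,
                               exclude = c(tr_smi, held_out,
                                           unlist(lapply(external_tests,
                                                         `[[`, "canonical_smiles"))))
      if (nrow(adds) > 1) {
        cutoff <- if (is.null(pipeline_spec$cluster_cutoff)) 0.6
                  else pipeline_spec$cluster_cutoff
        gfp <- morgan_fingerprints(adds$canonical_smiles, config)
        clus <- cluster_compounds(gfp, cutoff)
        adds <- adds[clus$centroids, , drop = FALSE]
      }
      stopifnot(!any(adds$canonical_smiles %in% held_out))  # leakage guard
      if (nrow(adds)) {
        add_fp <- morgan_fingerprints(adds$canonical_smiles, config)
        tr_bits <- rbind(tr_bits, add_fp$bits)
        tr_lab <- c(tr_lab, rep(minority, nrow(adds)))
      }
    } else if (strategy %in% c("enn", "smote_enn", "ksmote")) {
      fp_tr <- structure(list(ids = tr_smi, bits = tr_bits, config = config),
                         class = "fingerprint_matrix")
      rs <- traditional_resample(fp_tr, tr_lab, strategy, seed = seed_f)
      tr_bits <- rs$bits; tr_lab <- rs$labels
    }

    fp_tr <- structure(list(ids = paste0("t", seq_len(nrow(tr_bits))),
                            bits = tr_bits, config = config),
                       class = "fingerprint_matrix")
    model <- train_by_spec(pipeline_spec, fp_tr, tr_lab, seed_f)

    score_surface <- function(surface, fps_s, truth) {
      pr <- predict_proba(model, fps_s)
      m <- classification_metrics(truth, predict_label(pr), pr)
      cbind(data.frame(model = pipeline_spec$model, strategy = strategy,
                       fold = f, surface = surface,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(m)))
    }
    fp_te <- structure(list(ids = held_out,
                            bits = all_fp$bits[te_idx, , drop = FALSE],
                            config = config), class = "fingerprint_matrix")
    rows[[length(rows) + 1L]] <- score_surface("cv", fp_te, ds$label[te_idx])
    for (nm in names(ext_fp)) {
      rows[[length(rows) + 1L]] <-
        score_surface(nm, ext_fp[[nm]], external_tests[[nm]]$label)
    }
  }
  do.call(rbind, rows)
}

#' Reshape an evaluation report into a model-by-fold matrix for one metric
#'
#' @param report output of [cross_validate()] (possibly several, row-bound,
#'   with distinct `model`/`strategy` combinations).
#' @param metric metric column name.
#' @param surface which evaluation surface to extract (default `"cv"`).
#' @return matrix with one row per model-strategy combination.
#' @export
metric_table <- function(report, metric, surface = "cv") {
  sub <- report[report$surface == surface, , drop = FALSE]
  sub$id <- paste(sub$model, sub$strategy, sep = "+")
  ids <- unique(sub$id); folds <- sort(unique(sub$fold))
  out <- matrix(NA_real_, length(ids), length(folds),
                dimnames = list(ids, paste0("fold", folds)))
  for (r in seq_len(nrow(sub))) {
    out[sub$id[r], paste0("fold", sub$fold[r])] <- sub[[metric]][r]
  }
  out
}
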