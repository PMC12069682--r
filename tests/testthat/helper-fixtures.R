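# shared fixture builders (everything constructed in code; no data files)

# fingerprint_matrix from a list of on-bit index vectors
fp_from_bits <- function(onbits, n_bits = 64L) {
  bits <- t(vapply(onbits, function(ob) {
    v <- rep(FALSE, n_bits); v[ob] <- TRUE; v
  }, logical(n_bits)))
  structure(list(ids = paste0("c", seq_along(onbits)), bits = bits,
                 config = fp_config(n_bits, 2L)),
            class = "fingerprint_matrix")
}

# random fingerprint_matrix
fp_random <- function(n, n_bits = 64L, density = 0.2, seed = 1L) {
  set.seed(seed)
  bits <- matrix(runif(n * n_bits) < density, n, n_bits)
  structure(list(ids = paste0("c", seq_len(n)), bits = bits,
                 config = fp_config(n_bits, 2L)),
            class = "fingerprint_matrix")
}

# small raw bioactivity table
raw_bioactivity_fixture <- function() {
  data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("CCO", "CCN", "CCC"),
    activity_type = c("IC50", "Ki", "EC50"),
    relation = c("=", "=", "="),
    value = c(0.5, 20, 5),
    unit = c("uM", "uM", "uM"),
    stringsAsFactors = FALSE
  )
}

# independent naive metric computations (loop-based oracles)
naive_metrics <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == "active" && y_pred[i] == "active") tp <- tp + 1
    if (y_true[i] == "inactive" && y_pred[i] == "inactive") tn <- tn + 1
    if (y_true[i] == "inactive" && y_pred[i] == "active") fp <- fp + 1
    if (y_true[i] == "active" && y_pred[i] == "inactive") fn <- fn + 1
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(sensitivity = sens, specificity = spec, mcc = mcc,
    gmean = sqrt(sens * spec), accuracy = (tp + tn) / length(y_true))
}

# pairwise-comparison AUC oracle
naive_auc <- function(scores, y_true) {
  pos <- which(y_true == "active"); neg <- which(y_true == "inactive")
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# brute-force Butina oracle: neighbor counts then greedy sphere exclusion
naive_butina <- function(bits, cutoff) {
  n <- nrow(bits)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) sim[i, j] <- tanimoto(bits[i, ], bits[j, ])
  neigh <- sim >= (1 - cutoff); diag(neigh) <- FALSE
  deg <- rowSums(neigh)
  assigned <- rep(NA_integer_, n); cents <- integer(0); cl <- 0L
  for (i in order(-deg, seq_len(n))) {
    if (!is.na(assigned[i])) next
    cl <- cl + 1L
    mem <- c(i, which(neigh[i, ] & is.na(assigned)))
    assigned[mem] <- cl; cents <- c(cents, i)
  }
  list(assignment = assigned, centroids = cents)
}

# tiny, fast DNN config for tests (named overrides win over the defaults)
test_dnn_config <- function(n_bits = 64L, ...) {
  args <- utils::modifyList(
    list(input_width = n_bits, hidden_widths = c(24L, 12L),
         dropout_rate = 0.1, max_epochs = 120L, batch_size = 16L,
         early_stop_patience = 30L),
    list(...))
  do.call(dnn_config, args)
}
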