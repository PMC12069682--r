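# Minority-class augmentation: Butina sphere-exclusion clustering of
# generated compounds with centroid selection, plus classical resampling
# comparators (ENN, SMOTE-ENN, KSMOTE) operating in fingerprint space.

#' Butina sphere-exclusion clustering on Tanimoto distance
#'
#' Compounds are sorted by descending neighbor count (neighbors = compounds
#' within `distance_cutoff` in Tanimoto distance, 1 - similarity). Each
#' still-unassigned compound with the most neighbors founds a cluster
#' containing its unassigned neighbors; the founder is the cluster centroid.
#' Ties break on compound order, making the procedure deterministic.
#'
#' @param fps a `fingerprint_matrix`.
#' @param distance_cutoff Tanimoto distance radius in (0, 1).
#' @return list of class `cluster_result`: `assignment` (integer cluster id
#'   per compound) and `centroids` (row indices of founders, one per
#'   cluster).
#' @export
cluster_compounds <- function(fps, distance_cutoff = 0.6) {
  stopifnot(distance_cutoff > 0, distance_cutoff < 1)
  n <- nrow(fps$bits)
  stopifnot(n >= 1)
  sim <- tanimoto_matrix(fps$bits, fps$bits)
  neigh <- sim >= (1 - distance_cutoff)
  diag(neigh) <- FALSE
  degree <- rowSums(neigh)
  assignment <- rep(NA_integer_, n)
  centroids <- integer(0)
  cl <- 0L
  ord <- order(-degree, seq_len(n))
  for (i in ord) {
    if (!is.na(assignment[i])) next
    cl <- cl + 1L
    members <- c(i, which(neigh[i, ] & is.na(assignment)))
    assignment[members] <- cl
    centroids <- c(centroids, i)
  }
  structure(list(assignment = assignment, centroids = centroids,
                 n_clusters = cl, distance_cutoff = distance_cutoff),
            class = "cluster_result")
}

#' Cluster to (approximately) a requested number of clusters
#'
#' Bisects the Butina distance cutoff until the cluster count is as close as
#' possible to `target`; used when a fixed number of centroids is wanted.
#'
#' @param fps a `fingerprint_matrix`.
#' @param target desired cluster count.
#' @param iter bisection iterations.
#' @return the best `cluster_result` found.
#' @export
cluster_to_count <- function(fps, target, iter = 12L) {
  lo <- 0.02; hi <- 0.98
  best <- NULL
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    res <- cluster_compounds(fps, mid)
    if (is.null(best) ||
        abs(res$n_clusters - target) < abs(best$n_clusters - target)) {
      best <- res
    }
    if (res$n_clusters == target) break
    # larger radius -> fewer clusters
    if (res$n_clusters > target) lo <- mid else hi <- mid
  }
  best
}

#' Add generated compounds to a dataset under one label
#'
#' Appends the additions with their recorded source and re-applies the full
#' dedup rules: within-class duplicates collapse, and a generated compound
#' colliding with the opposite class removes both records.
#'
#' @param base a `labeled_dataset`.
#' @param additions data.frame with `canonical_smiles` (and optionally
#'   `compound_id`, `source`) as produced by [filter_generated()].
#' @param label class to assign to the additions.
#' @return the augmented `labeled_dataset`.
#' @export
augment_dataset <- function(base, additions, label = "inactive") {
  label <- match.arg(label, c("active", "inactive"))
  if (!nrow(additions)) return(base)
  src <- if ("source" %in% names(additions)) additions$source else "generated"
  ids <- if ("compound_id" %in% names(additions)) additions$compound_id
         else additions$canonical_smiles
  labeled_dataset(
    c(base$canonical_smiles, additions$canonical_smiles),
    c(base$label, rep(label, nrow(additions))),
    compound_id = c(base$compound_id, ids),
    source = c(base$source, rep(src, length.out = nrow(additions)))
  )
}

# brute-force k nearest neighbors by Euclidean distance (binary vectors),
# excluding self; returns index matrix n x k
knn_index <- function(X, k) {
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Classical resampling comparators in fingerprint space
#'
#' Standard imbalance corrections operating on the feature vectors rather
#' than on molecules: `enn` (edited nearest neighbours; removes majority
#' points misclassified by their 3 nearest neighbours), `smote_enn` (SMOTE
#' oversampling of the minority followed by ENN cleaning of both classes)
#' and `ksmote` (k-means-guided SMOTE: interpolation within minority k-means
#' clusters). SMOTE interpolates continuous vectors, which are binarized at
#' 0.5 so downstream classifiers keep consuming binary fingerprints;
#' synthetic points carry no SMILES.
#'
#' @param fps training `fingerprint_matrix`.
#' @param labels class labels aligned with `fps$ids`.
#' @param method one of `"enn"`, `"smote_enn"`, `"ksmote"`.
#' @param seed RNG seed.
#' @param k_neighbors SMOTE interpolation neighbours.
#' @return list with `bits` (logical matrix), `labels`, `source`
#'   (`"public"`/`"synthetic"`), and `config`.
#' @export
traditional_resample <- function(fps, labels, method = c("enn", "smote_enn", "ksmote"),
                                 seed = 1L, k_neighbors = 5L) {
  method <- match.arg(method)
  X <- fps$bits * 1
  y <- as.character(labels)
  minority <- names(which.min(table(y)))
  n_min <- sum(y == minority)
  if (method != "enn" && n_min < k_neighbors + 1L) {
    stop(method, " requires at least ", k_neighbors + 1L,
         " minority compounds (k_neighbors = ", k_neighbors, ")")
  }
  if (method == "enn" && n_min < 4L) {
    stop("enn requires at least 4 compounds per class (3-NN editing)")
  }
  src <- rep("public", length(y))

  smote <- function(X, y, n_new) {
    idx_min <- which(y == minority)
    Xm <- X[idx_min, , drop = FALSE]
    nn <- knn_index(Xm, min(k_neighbors, nrow(Xm) - 1L))
    base_pick <- sample(nrow(Xm), n_new, replace = TRUE)
    neigh_pick <- vapply(base_pick, function(i) nn[i, sample(ncol(nn), 1L)],
                         integer(1))
    lam <- stats::runif(n_new)
    Xnew <- Xm[base_pick, , drop = FALSE] * (1 - lam) +
      Xm[neigh_pick, , drop = FALSE] * lam
    (Xnew >= 0.5) * 1
  }
  enn_clean <- function(X, y, src) {
    nn <- knn_index(X, 3L)
    vote <- vapply(seq_len(nrow(X)), function(i) {
      names(which.max(table(y[nn[i, ]])))
    }, character(1))
    keep <- vote == y
    list(X = X[keep, , drop = FALSE], y = y[keep], src = src[keep])
  }

  out <- with_seed(seed, switch(method,
    enn = {
      # undersampling direction: only majority points are eligible for removal
      nn <- knn_index(X, 3L)
      vote <- vapply(seq_len(nrow(X)), function(i) {
        names(which.max(table(y[nn[i, ]])))
      }, character(1))
      keep <- y == minority | vote == y
      list(X = X[keep, , drop = FALSE], y = y[keep], src = src[keep])
    },
    smote_enn = {
      n_new <- sum(y != minority) - n_min
      Xs <- smote(X, y, n_new)
      X2 <- rbind(X, Xs)
      y2 <- c(y, rep(minority, n_new))
      src2 <- c(src, rep("synthetic", n_new))
      enn_clean(X2, y2, src2)
    },
    ksmote = {
      idx_min <- which(y == minority)
      Xm <- X[idx_min, , drop = FALSE]
      n_new <- sum(y != minority) - n_min
      kcl <- max(1L, min(3L, floor(nrow(Xm) / (k_neighbors + 1L))))
      km <- stats::kmeans(Xm, centers = kcl, nstart = 3L)
      new_rows <- lapply(seq_len(kcl), function(ci) {
        members <- which(km$cluster == ci)
        quota <- round(n_new * length(members) / nrow(Xm))
        if (quota == 0L || length(members) < 2L) return(NULL)
        nn_k <- min(k_neighbors, length(members) - 1L)
        nn <- knn_index(Xm[members, , drop = FALSE], nn_k)
        base_pick <- sample(length(members), quota, replace = TRUE)
        neigh_pick <- vapply(base_pick, function(i) nn[i, sample(nn_k, 1L)],
                             integer(1))
        lam <- stats::runif(quota)
        Xn <- Xm[members[base_pick], , drop = FALSE] * (1 - lam) +
          Xm[members[neigh_pick], , drop = FALSE] * lam
        (Xn >= 0.5) * 1
      })
      Xs <- do.call(rbind, new_rows)
      n_add <- if (is.null(Xs)) 0L else nrow(Xs)
      list(X = rbind(X, Xs), y = c(y, rep(minority, n_add)),
           src = c(src, rep("synthetic", n_add)))
    }
  ))
  list(bits = out$X > 0, labels = out$y, source = out$src, config = fps$config)
}
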