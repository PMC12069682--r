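test_that("Butina clustering handles degenerate geometries", {
  # all identical -> one cluster, one centroid
  fps <- fp_from_bits(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  res <- cluster_compounds(fps, 0.6)
  expect_equal(res$n_clusters, 1)
  expect_length(res$centroids, 1)
  # all pairwise distances above the cutoff -> all singleton centroids
  fps2 <- fp_from_bits(list(1:3, 11:13, 21:23, 31:33))
  res2 <- cluster_compounds(fps2, 0.4)
  expect_equal(res2$n_clusters, 4)
  expect_identical(sort(res2$centroids), 1:4)
})

test_that("a two-group fixture recovers both clusters with correct centroids", {
  # group 1: rows 1-3 tightly similar; group 2: rows 4-5; no cross-links
  fps <- fp_from_bits(list(c(1, 2, 3, 4), c(1, 2, 3, 5), c(1, 2, 3, 4, 5),
                           c(40, 41, 42), c(40, 41, 43)))
  res <- cluster_compounds(fps, 0.6)
  oracle <- naive_butina(fps$bits, 0.6)
  expect_equal(res$n_clusters, 2)
  expect_identical(res$assignment, oracle$assignment)
  expect_identical(res$centroids, oracle$centroids)
  # founders belong to their own cluster
  for (i in seq_along(res$centroids)) {
    expect_equal(res$assignment[res$centroids[i]], i)
  }
})

test_that("clustering invariants hold on random fingerprint sets", {
  for (seed in 1:25) {
    fps <- fp_random(20, n_bits = 64, density = 0.25, seed = seed)
    res <- cluster_compounds(fps, 0.6)
    # partition: every compound assigned exactly once
    expect_false(anyNA(res$assignment))
    expect_equal(length(res$centroids), res$n_clusters)
    expect_equal(sort(unique(res$assignment)), seq_len(res$n_clusters))
    # centroid coverage: members are within the cutoff of their centroid
    # or are centroids themselves
    for (i in seq_len(20)) {
      cent <- res$centroids[res$assignment[i]]
      d <- 1 - tanimoto(fps$bits[i, ], fps$bits[cent, ])
      expect_true(i %in% res$centroids || d <= 0.6)
    }
    # agreement with the brute-force oracle
    oracle <- naive_butina(fps$bits, 0.6)
    expect_identical(res$assignment, oracle$assignment)
  }
})

test_that("cutoff bisection approaches a requested cluster count", {
  fps <- fp_random(40, n_bits = 64, density = 0.3, seed = 2)
  res <- cluster_to_count(fps, 8)
  expect_lte(abs(res$n_clusters - 8), 3)
})

test_that("augmentation appends, deduplicates and resolves conflicts", {
  base <- labeled_dataset(c("CCO", "CCN", "CCC"),
                          c("active", "active", "inactive"))
  expect_identical(augment_dataset(base, data.frame(canonical_smiles = character(0))),
                   base)
  # duplicate of an existing inactive: unchanged
  aug <- augment_dataset(base, data.frame(canonical_smiles = "CCC"), "inactive")
  expect_equal(nrow(aug), 3)
  # collision with an existing active removes both
  aug2 <- augment_dataset(base, data.frame(canonical_smiles = "CCO"), "inactive")
  expect_false("CCO" %in% aug2$canonical_smiles)
  expect_equal(nrow(aug2), 2)
  # provenance column carries through
  aug3 <- augment_dataset(base, data.frame(canonical_smiles = "CCCC"), "inactive")
  expect_identical(aug3$source[aug3$canonical_smiles == "CCCC"], "generated")
})

test_that("centroid augmentation at study scale adds exactly the centroids", {
  # 275 base inactives + 1,604 collision-free centroid additions -> 1,879
  base <- labeled_dataset(sprintf("base%d", 1:275), rep("inactive", 275))
  adds <- data.frame(canonical_smiles = sprintf("cent%d", 1:1604),
                     stringsAsFactors = FALSE)
  aug <- augment_dataset(base, adds, "inactive")
  expect_equal(sum(aug$label == "inactive"), 1879)
})

test_that("classical resamplers move class counts in the right direction", {
  set.seed(3)
  bits <- rbind(matrix(runif(100 * 32) < 0.3, 100, 32),
                matrix(runif(10 * 32) < 0.7, 10, 32))
  fps <- structure(list(ids = paste0("c", 1:110), bits = bits,
                        config = fp_config(64, 2)), class = "fingerprint_matrix")
  labels <- rep(c("active", "inactive"), c(100, 10))
  # ENN only removes (majority side)
  enn <- traditional_resample(fps, labels, "enn", seed = 1)
  expect_lte(length(enn$labels), 110)
  expect_equal(sum(enn$labels == "inactive"), 10)
  # SMOTE-ENN oversamples the minority before cleaning
  se <- traditional_resample(fps, labels, "smote_enn", seed = 1)
  expect_gt(sum(se$labels == "inactive"), 10)
  expect_true(all(se$bits %in% c(TRUE, FALSE)))
  expect_true(any(se$source == "synthetic"))
  # KSMOTE oversamples within k-means clusters
  ks <- traditional_resample(fps, labels, "ksmote", seed = 1)
  expect_gt(sum(ks$labels == "inactive"), 10)
  # determinism
  se2 <- traditional_resample(fps, labels, "smote_enn", seed = 1)
  expect_identical(se$bits, se2$bits)
  # neighbor requirements are named in errors
  tiny <- structure(list(ids = paste0("c", 1:8), bits = bits[c(1:4, 101:104), ],
                         config = fp_config(64, 2)), class = "fingerprint_matrix")
  expect_error(traditional_resample(tiny, rep(c("active", "inactive"), each = 4),
                                    "smote_enn"), "minority")
})
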