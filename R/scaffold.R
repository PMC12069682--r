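# Bemis-Murcko scaffolds, deterministic scaffold splitting, stratified folds.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Minimal V2000 molfile writer for scaffold subgraphs (coordinates zeroed;
# implicit hydrogens are restored by the reader).
write_v2000 <- function(title, elements, bonds) {
  n_at <- length(elements); n_bd <- nrow(bonds)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, elements)
  bond_lines <- if (n_bd) sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3])
                else character(0)
  c(title, "", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd),
    atom_lines, bond_lines, "M  END", "$$$$")
}

# Prune side chains from one molecule's connection table: repeatedly delete
# terminal atoms attached by a single bond. Atoms double- or triple-bonded
# to the remaining framework (e.g. carbonyl oxygens) are retained, matching
# the usual Murcko-framework convention.
prune_to_framework <- function(elements, bonds) {
  keep <- rep(TRUE, length(elements))
  repeat {
    idx <- which(keep)
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = length(elements))
    # degrees restricted to live bonds
    live <- keep[bonds[, 1]] & keep[bonds[, 2]]
    deg <- tabulate(c(bonds[live, 1], bonds[live, 2]), nbins = length(elements))
    term <- which(keep & deg == 1)
    drop <- term[vapply(term, function(a) {
      b <- which(live & (bonds[, 1] == a | bonds[, 2] == a))
      bonds[b[1], 3] == 1
    }, logical(1))]
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  keep
}

#' Bemis-Murcko scaffold keys
#'
#' Computes the canonical SMILES of each molecule's Bemis-Murcko framework
#' (ring systems plus linkers, side chains removed; exocyclic multiple-bonded
#' atoms retained). Acyclic molecules map to the reserved empty key `""`.
#'
#' @param smiles character vector of canonical SMILES.
#' @return character vector of scaffold keys aligned with the input.
#' @export
murcko_scaffold <- function(smiles) {
  res <- rep("", length(smiles))
  can <- ob_canonical(smiles)
  if (anyNA(can)) stop("unparsable SMILES passed to murcko_scaffold")
  cyclic <- which(ring_count_smiles(can) > 0)
  if (!length(cyclic)) return(res)

  sdf_out <- ob_call(smiles[cyclic], "sdf")
  sdf_file <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf_file), add = TRUE)
  writeLines(sdf_out, sdf_file)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_file))
  titles <- vapply(seq_along(ChemmineR::cid(sdfs)), function(i) {
    ChemmineR::header(sdfs[[i]])[["Molecule_Name"]]
  }, character(1))
  pos <- match(attr(sdf_out, "ids"), titles)
  if (anyNA(pos)) stop("scaffold computation failed for some molecules")

  blocks <- unlist(lapply(seq_along(cyclic), function(j) {
    mol <- sdfs[[pos[j]]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    bonds <- matrix(as.integer(bb[, 1:3]), ncol = 3)
    keep <- prune_to_framework(elements, bonds)
    remap <- cumsum(keep)
    live <- keep[bonds[, 1]] & keep[bonds[, 2]]
    nb <- cbind(remap[bonds[live, 1]], remap[bonds[live, 2]], bonds[live, 3])
    write_v2000(paste0("m", j), elements[keep], nb)
  }))
  scaf_file <- tempfile(fileext = ".sdf")
  on.exit(unlink(scaf_file), add = TRUE)
  writeLines(blocks, scaf_file)
  out <- suppressWarnings(system2(ob_binary(), c("-isdf", scaf_file, "-ocan", "-e"),
                                  stdout = TRUE, stderr = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  got <- match(trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                             character(1))),
               paste0("m", seq_along(cyclic)))
  if (anyNA(got) || length(got) != length(cyclic)) {
    stop("scaffold canonicalization failed")
  }
  res[cyclic[got]] <- vapply(parts, `[`, character(1), 1)
  res
}

#' Deterministic scaffold-based train/test split
#'
#' Groups compounds by Bemis-Murcko scaffold, sorts the groups by descending
#' size breaking ties lexicographically on the scaffold key, and assigns
#' whole groups greedily to the training set until the training fraction is
#' reached; remaining groups form the test set. No scaffold key ever spans
#' both partitions, and the procedure involves no randomness.
#'
#' @param ds a `labeled_dataset`.
#' @param train_fraction target fraction of compounds in the training set.
#' @return list of class `split_result`: `train`, `test` (both
#'   `labeled_dataset`), and `scaffold_assignment` (named character vector,
#'   canonical SMILES -> scaffold key).
#' @export
scaffold_split <- function(ds, train_fraction = 0.8) {
  stopifnot(nrow(ds) > 0, train_fraction > 0, train_fraction < 1)
  keys <- murcko_scaffold(ds$canonical_smiles)
  names(keys) <- ds$canonical_smiles
  tab <- table(keys)
  sizes <- as.integer(tab)
  groups <- names(tab)
  ord <- order(-sizes, groups)
  sizes <- sizes[ord]; groups <- groups[ord]
  target <- train_fraction * nrow(ds)
  in_train_key <- character(0)
  n_train <- 0
  for (i in seq_along(groups)) {
    if (n_train >= target) break
    in_train_key <- c(in_train_key, groups[i])
    n_train <- n_train + sizes[i]
  }
  train_rows <- keys %in% in_train_key
  if (all(train_rows)) {
    warning("a dominant scaffold group forced an empty test set")
  }
  sub <- function(rows) {
    d <- ds[rows, , drop = FALSE]
    labeled_dataset(d$canonical_smiles, d$label, d$compound_id, d$source)
  }
  structure(list(train = sub(train_rows), test = sub(!train_rows),
                 scaffold_assignment = keys),
            class = "split_result")
}

#' Remove train compounds whose fingerprints collide with the test set
#'
#' A post-split hygiene step: any training compound with a fingerprint
#' identical to some test compound's fingerprint is dropped from the
#' training set; the test set is untouched.
#'
#' @param split a `split_result`.
#' @param config fingerprint configuration used for the identity check.
#' @return the cleaned `split_result`, with attribute `n_removed`.
#' @export
remove_cross_split_duplicates <- function(split, config = fp_config()) {
  if (!nrow(split$train) || !nrow(split$test)) {
    attr(split, "n_removed") <- 0L
    return(split)
  }
  fp_tr <- morgan_fingerprints(split$train$canonical_smiles, config)
  fp_te <- morgan_fingerprints(split$test$canonical_smiles, config)
  tr_key <- apply(fp_tr$bits, 1, paste, collapse = "")
  te_key <- apply(fp_te$bits, 1, paste, collapse = "")
  hit <- tr_key %in% te_key
  d <- split$train[!hit, , drop = FALSE]
  split$train <- labeled_dataset(d$canonical_smiles, d$label, d$compound_id, d$source)
  attr(split, "n_removed") <- sum(hit)
  split
}

#' Stratified k-fold assignment
#'
#' Each class is independently permuted under the seed and dealt round-robin
#' to the folds, keeping every fold's active:inactive ratio within one
#' compound per class of the global ratio.
#'
#' @param ds a `labeled_dataset`.
#' @param k number of folds.
#' @param seed RNG seed; same seed reproduces the same plan.
#' @return list of class `fold_plan`: `k`, `seed`, and `fold_of` (integer
#'   vector in `1..k` aligned with the rows of `ds`).
#' @export
stratified_kfold <- function(ds, k = 10L, seed = 1L) {
  k <- as.integer(k)
  counts <- table(ds$label)
  if (any(counts < k)) {
    stop("each class must have at least k members (k = ", k, ")")
  }
  fold_of <- integer(nrow(ds))
  with_seed(seed, {
    for (cl in names(counts)) {
      rows <- which(ds$label == cl)
      perm <- sample(rows)
      fold_of[perm] <- rep_len(seq_len(k), length(perm))
    }
  })
  structure(list(k = k, seed = seed, fold_of = fold_of), class = "fold_plan")
}
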