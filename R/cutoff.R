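# Class-overlap analysis as the inactive cutoff varies: for each candidate
# cutoff, relabel, re-deduplicate, fingerprint, and count actives whose
# nearest inactive exceeds a Tanimoto similarity threshold.

#' Count actives overlapping the inactive class
#'
#' Number of actives whose maximum Tanimoto similarity to any inactive is
#' strictly greater than `threshold`.
#'
#' @param actives,inactives `fingerprint_matrix` objects with identical
#'   fingerprint configuration.
#' @param threshold similarity threshold in (0, 1).
#' @return integer count (0 with a warning when the inactive set is empty).
#' @export
max_similarity_overlap <- function(actives, inactives, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (!identical(actives$config, inactives$config)) {
    stop("fingerprint configurations differ between the two sets")
  }
  if (!nrow(actives$bits)) return(0L)
  if (!nrow(inactives$bits)) {
    warning("empty inactive set; overlap undefined, returning 0")
    return(0L)
  }
  sim <- tanimoto_matrix(actives$bits, inactives$bits)
  sum(apply(sim, 1, max) > threshold)
}

#' Scan inactive cutoffs and report class sizes and overlap
#'
#' Reproduces the cutoff-evaluation procedure: with the active cutoff fixed,
#' each candidate inactive cutoff relabels the raw bioactivities, the full
#' dedup (including cross-class conflict removal) is re-run, and the number
#' of actives with maximum Tanimoto similarity above the threshold to any
#' inactive is counted.
#'
#' @param raw data.frame of raw bioactivities (the schema of
#'   [read_bioactivities()], with SMILES already standardized or not).
#' @param active_cutoff_uM fixed active cutoff (micromolar).
#' @param inactive_cutoffs_uM ascending vector of inactive cutoffs to scan.
#' @param threshold Tanimoto overlap threshold.
#' @param config fingerprint configuration.
#' @return data.frame with one row per cutoff: `active_cutoff_uM`,
#'   `inactive_cutoff_uM`, `n_active`, `n_inactive`, `n_overlap`.
#' @export
cutoff_scan <- function(raw, active_cutoff_uM = 1,
                        inactive_cutoffs_uM = 2:10, threshold = 0.5,
                        config = fp_config()) {
  if (any(inactive_cutoffs_uM < active_cutoff_uM)) {
    stop("all inactive cutoffs must be >= the active cutoff")
  }
  inactive_cutoffs_uM <- sort(inactive_cutoffs_uM)
  std <- standardize_smiles(raw$smiles, compound_id = raw$compound_id)
  ok <- std$ok
  fp_cache <- NULL
  all_smi <- unique(std$canonical_smiles[ok])
  if (length(all_smi)) {
    fp_cache <- morgan_fingerprints(all_smi, config)
  }
  rows <- lapply(inactive_cutoffs_uM, function(cut) {
    cfg <- curation_config(active_cutoff_uM, cut)
    lab <- label_activity(raw$value[ok], raw$relation[ok], raw$unit[ok], cfg)
    use <- lab %in% c("active", "inactive")
    ds <- labeled_dataset(std$canonical_smiles[ok][use], lab[use],
                          compound_id = std$compound_id[ok][use])
    sel <- function(cl) {
      idx <- match(ds$canonical_smiles[ds$label == cl], fp_cache$ids)
      structure(list(ids = fp_cache$ids[idx],
                     bits = fp_cache$bits[idx, , drop = FALSE],
                     config = config), class = "fingerprint_matrix")
    }
    n_act <- sum(ds$label == "active"); n_inact <- sum(ds$label == "inactive")
    ov <- if (n_act && n_inact) {
      max_similarity_overlap(sel("active"), sel("inactive"), threshold)
    } else 0L
    data.frame(active_cutoff_uM = active_cutoff_uM, inactive_cutoff_uM = cut,
               n_active = n_act, n_inactive = n_inact, n_overlap = ov)
  })
  do.call(rbind, rows)
}
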