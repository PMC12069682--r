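# Curation: dual-cutoff activity labeling and deduplicated labeled datasets.
#
# Input schema (CSV/TSV): compound_id, smiles, activity_type, relation,
# value, unit. Activity types EC50/IC50/Ki are pooled: the model predicts
# interaction with the target, not its pharmacological mode.

#' Curation configuration (dual activity cutoffs)
#'
#' Compounds at or below `active_cutoff_uM` are actives, at or above
#' `inactive_cutoff_uM` inactives; the band in between is excluded as
#' ambiguous. Defaults follow the common 1/10 micromolar convention.
#'
#' @param active_cutoff_uM upper potency bound for actives, in micromolar.
#' @param inactive_cutoff_uM lower bound for inactives, in micromolar.
#' @export
curation_config <- function(active_cutoff_uM = 1, inactive_cutoff_uM = 10) {
  stopifnot(active_cutoff_uM > 0, inactive_cutoff_uM >= active_cutoff_uM)
  structure(list(active_cutoff_uM = active_cutoff_uM,
                 inactive_cutoff_uM = inactive_cutoff_uM),
            class = "curation_config")
}

.unit_to_uM <- c(nM = 1e-3, uM = 1, "µM" = 1, M = 1e6)

#' Assign activity-class labels from bioactivity measurements
#'
#' Values are converted to micromolar and compared against the dual cutoffs.
#' Qualified values ("greater than" at or beyond the inactive cutoff) count
#' as inactives even without an absolute measurement; "less than" bounds
#' above the active cutoff are uninformative and excluded.
#'
#' @param value numeric measured values (EC50/IC50/Ki), strictly positive.
#' @param relation one of `=`, `>`, `<`, `>=`, `<=` per value (unicode
#'   `≥`/`≤` accepted).
#' @param unit one of `nM`, `uM` (or `µM`), `M` per value.
#' @param cfg a [curation_config()].
#' @return character vector in `{"active", "inactive", "excluded"}`.
#' @export
label_activity <- function(value, relation, unit, cfg = curation_config()) {
  relation <- gsub("≥", ">=", gsub("≤", "<=", as.character(relation)))
  if (!all(relation %in% c("=", ">", "<", ">=", "<="))) {
    stop("unknown relation: ",
         paste(unique(setdiff(relation, c("=", ">", "<", ">=", "<="))), collapse = ", "))
  }
  conv <- .unit_to_uM[as.character(unit)]
  if (anyNA(conv)) {
    stop("unknown unit: ", paste(unique(unit[is.na(conv)]), collapse = ", "))
  }
  if (any(!is.finite(value) | value <= 0)) stop("bioactivity values must be positive")
  v <- value * conv
  lab <- rep("excluded", length(v))
  lab[v <= cfg$active_cutoff_uM & relation %in% c("=", "<", "<=")] <- "active"
  lab[v >= cfg$inactive_cutoff_uM & relation %in% c("=", ">", ">=")] <- "inactive"
  lab
}

#' Construct a labeled dataset with dedup guarantees
#'
#' One record per canonical SMILES per class (first occurrence in input
#' order wins); any SMILES appearing under both labels is removed from both
#' classes entirely.
#'
#' @param canonical_smiles character vector of canonical SMILES.
#' @param label character vector in `{"active", "inactive"}`.
#' @param compound_id optional ids.
#' @param source provenance per record (`public`/`generated`/`synthetic`).
#' @return a `labeled_dataset`: data.frame with columns `compound_id`,
#'   `canonical_smiles`, `label`, `source`, plus attributes `n_conflict`
#'   (cross-class exclusions) and `n_dup` (within-class duplicates dropped).
#' @export
labeled_dataset <- function(canonical_smiles, label, compound_id = NULL,
                            source = "public") {
  stopifnot(all(label %in% c("active", "inactive")))
  if (is.null(compound_id)) compound_id <- canonical_smiles
  if (length(source) == 1L) source <- rep(source, length(canonical_smiles))
  df <- data.frame(compound_id = as.character(compound_id),
                   canonical_smiles = as.character(canonical_smiles),
                   label = as.character(label),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("canonical_smiles", "label")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  both <- intersect(df$canonical_smiles[df$label == "active"],
                    df$canonical_smiles[df$label == "inactive"])
  n_conflict <- sum(df$canonical_smiles %in% both)
  df <- df[!df$canonical_smiles %in% both, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_dup = n_dup, n_conflict = n_conflict,
            class = c("labeled_dataset", "data.frame"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d actives, %d inactives\n",
              sum(x$label == "active"), sum(x$label == "inactive")))
  invisible(x)
}

#' Read a raw bioactivity table
#'
#' @param path CSV or TSV file with header columns `compound_id`, `smiles`,
#'   `activity_type`, `relation`, `value`, `unit`.
#' @return data.frame of raw bioactivities.
#' @export
read_bioactivities <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  required <- c("compound_id", "smiles", "activity_type", "relation",
                "value", "unit")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) && !all(df$activity_type %in% c("EC50", "IC50", "Ki"))) {
    stop("activity_type must be one of EC50, IC50, Ki")
  }
  df
}

#' Curate a raw bioactivity table into a labeled dataset
#'
#' Pipeline: standardize SMILES, label with dual cutoffs, deduplicate.
#' A curation log (counts per disposition) is attached as attribute `log`.
#'
#' @param path input CSV/TSV path (see [read_bioactivities()]).
#' @param cfg a [curation_config()].
#' @return a `labeled_dataset` (possibly empty) with attribute `log`.
#' @export
build_dataset <- function(path, cfg = curation_config()) {
  raw <- read_bioactivities(path)
  if (!nrow(raw)) {
    warning("empty bioactivity table: ", path)
    ds <- labeled_dataset(character(0), character(0))
    attr(ds, "log") <- list(n_input = 0L)
    return(ds)
  }
  curate_bioactivities(raw, cfg)
}

#' @rdname build_dataset
#' @param raw data.frame in the raw bioactivity schema.
#' @export
curate_bioactivities <- function(raw, cfg = curation_config()) {
  std <- standardize_smiles(raw$smiles, compound_id = raw$compound_id)
  lab <- label_activity(raw$value, raw$relation, raw$unit, cfg)
  usable <- std$ok & lab %in% c("active", "inactive")
  ds <- labeled_dataset(std$canonical_smiles[usable], lab[usable],
                        compound_id = std$compound_id[usable])
  attr(ds, "log") <- list(
    n_input = nrow(raw),
    n_rejected = sum(!std$ok),
    reject_reasons = table(std$reason[!std$ok]),
    n_excluded_ambiguous = sum(std$ok & lab == "excluded"),
    n_within_class_duplicates = attr(ds, "n_dup"),
    n_cross_class_conflicts = attr(ds, "n_conflict")
  )
  ds
}

#' Write a curated dataset to CSV
#'
#' @param ds a `labeled_dataset`.
#' @param path output CSV path (columns `compound_id`, `canonical_smiles`,
#'   `label`, `source`).
#' @param log_path optional path for the curation log as JSON.
#' @export
write_dataset <- function(ds, path, log_path = NULL) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  if (!is.null(log_path)) {
    log <- attr(ds, "log")
    if (!is.null(log)) log$reject_reasons <- as.list(log$reject_reasons)
    jsonlite::write_json(log, log_path, auto_unbox = TRUE)
  }
  invisible(path)
}
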