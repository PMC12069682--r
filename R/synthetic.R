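# Seeded generator of two-class SMILES datasets with scaffold-family
# structure. Molecules are built from a fixed grammar -- six ring cores
# decorated with 1-3 substituents at enumerated positions -- so every
# emitted SMILES is valid by construction and carries a genuine
# Bemis-Murcko scaffold. Class labels correlate with scaffold family
# (the separability mechanism); `cross_family_mixing` places a fraction of
# inactives inside active-dominant families to dial the task difficulty.

.syn_cores <- list(
  benzene     = list(template = "c1c{A}c{B}c{C}cc1", sites = 3L),
  pyridine    = list(template = "c1c{A}c{B}c{C}cn1", sites = 3L),
  pyrimidine  = list(template = "c1c{A}c{B}nc{C}n1", sites = 3L),
  indole      = list(template = "c1cc{C}c2c(c1)c{A}c{B}[nH]2", sites = 3L),
  piperidine  = list(template = "C1C{A}C{B}C{C}CN1", sites = 3L),
  cyclohexane = list(template = "C1C{A}C{B}C{C}CC1", sites = 3L)
)

# 12 substituents; the two ring-bearing ones (phenyl, cyclopropyl; ring
# closure digit 3 avoids colliding with core ring digits) diversify the
# Bemis-Murcko scaffolds within each family so scaffold splitting operates
# on many groups rather than one per core.
.syn_subs <- c("C", "CC", "CCC", "CO", "OC", "O", "N", "F", "Cl", "C#N",
               "c3ccccc3", "C3CC3")

# enumerate every decorated SMILES of one core in a fixed deterministic
# order: site subsets by increasing size, substituent indices odometer-style
enumerate_family <- function(core) {
  tmpl <- core$template; ns <- core$sites
  site_names <- c("A", "B", "C")[seq_len(ns)]
  out <- character(0)
  for (sz in 1:ns) {
    subsets <- utils::combn(seq_len(ns), sz, simplify = FALSE)
    for (ss in subsets) {
      grid <- expand.grid(rep(list(seq_along(.syn_subs)), sz))
      for (r in seq_len(nrow(grid))) {
        s <- tmpl
        for (p in seq_len(ns)) {
          ph <- paste0("{", site_names[p], "}")
          pos <- match(p, ss)
          rep_with <- if (is.na(pos)) "" else
            paste0("(", .syn_subs[grid[r, pos]], ")")
          s <- sub(ph, rep_with, s, fixed = TRUE)
        }
        out <- c(out, s)
      }
    }
  }
  out
}

#' Synthetic dataset specification
#'
#' @param n_active,n_inactive class sizes of the main (training-side)
#'   dataset.
#' @param n_scaffold_families number of scaffold families used (2..6).
#' @param cross_family_mixing fraction of inactives drawn from
#'   active-dominant families, in \[0, 1\]; 0 makes scaffold families
#'   perfectly class-pure.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the spec.
#' @param hts_test also emit an inversely imbalanced screening-style test
#'   set (inactive:active about `hts_ratio`:1).
#' @param hts_ratio inactive:active ratio of the screening test set.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active, n_inactive, n_scaffold_families = 6L,
                           cross_family_mixing = 0.1, seed = 1L,
                           hts_test = FALSE, hts_ratio = 75L) {
  stopifnot(n_active >= 1, n_inactive >= 1,
            n_scaffold_families >= 2, n_scaffold_families <= length(.syn_cores),
            cross_family_mixing >= 0, cross_family_mixing <= 1)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 n_scaffold_families = as.integer(n_scaffold_families),
                 cross_family_mixing = cross_family_mixing,
                 seed = as.integer(seed), hts_test = isTRUE(hts_test),
                 hts_ratio = as.integer(hts_ratio)),
            class = "synthetic_spec")
}

# draw `n` unique canonical SMILES from the pooled per-family enumerations,
# excluding `used`; returns data.frame(smiles, family)
draw_from_families <- function(pools, families, n, used) {
  # per-family quota for roughly even coverage, topped up from whatever
  # capacity remains when some family pool runs short
  avail <- lapply(families, function(f) setdiff(pools[[f]], used))
  names(avail) <- families
  total <- sum(lengths(avail))
  if (total < n) {
    stop("synthetic grammar capacity exceeded: requested ", n,
         " more compounds but only ", total, " remain")
  }
  per <- ceiling(n / length(families)) + 2L
  take <- character(0); fam <- character(0)
  for (f in families) {
    got <- utils::head(avail[[f]], per)
    take <- c(take, got); fam <- c(fam, rep(f, length(got)))
    avail[[f]] <- setdiff(avail[[f]], got)
  }
  while (length(take) < n) {
    for (f in families) {
      need <- n - length(take)
      if (need <= 0) break
      got <- utils::head(avail[[f]], max(per, need))
      take <- c(take, got); fam <- c(fam, rep(f, length(got)))
      avail[[f]] <- setdiff(avail[[f]], got)
    }
  }
  ord <- sample.int(length(take))
  data.frame(smiles = take[ord][seq_len(n)], family = fam[ord][seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-class SMILES dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a `labeled_dataset`, `source = "synthetic"`),
#'   `hts_test` (a second `labeled_dataset` or `NULL`), and `family`
#'   (named character vector, canonical SMILES -> scaffold family).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fam_names <- names(.syn_cores)[seq_len(spec$n_scaffold_families)]
  active_fams <- fam_names[seq_len(ceiling(length(fam_names) / 2))]
  inactive_fams <- setdiff(fam_names, active_fams)

  n_hts_a <- if (spec$hts_test) max(2L, round(spec$n_active / 20)) else 0L
  total_need <- spec$n_active + spec$n_inactive +
    n_hts_a * (1L + spec$hts_ratio)

  with_seed(spec$seed, {
    # canonical, deduplicated, seed-shuffled pool per family; only as much
    # of the enumeration is canonicalized as the request plausibly needs,
    # falling back to the full enumeration if deduplication collapses it
    raw_perm <- lapply(fam_names, function(f) {
      sample(enumerate_family(.syn_cores[[f]]))
    })
    names(raw_perm) <- fam_names
    build_pools <- function(cap) {
      pools <- lapply(raw_perm, function(perm) {
        can <- ob_canonical(utils::head(perm, cap))
        if (anyNA(can)) stop("internal grammar error: invalid SMILES emitted")
        unique(can)
      })
      names(pools) <- fam_names
      pools
    }
    cap <- ceiling(4 * total_need / length(fam_names)) + 100L
    pools <- build_pools(cap)

    draw_all <- function(pools) {
      n_mix <- round(spec$cross_family_mixing * spec$n_inactive)
      used <- character(0)
      act <- draw_from_families(pools, active_fams, spec$n_active, used)
      used <- c(used, act$smiles)
      inact_pure <- draw_from_families(pools, inactive_fams,
                                       spec$n_inactive - n_mix, used)
      used <- c(used, inact_pure$smiles)
      inact_mix <- if (n_mix > 0) {
        d <- draw_from_families(pools, active_fams, n_mix, used)
        used <- c(used, d$smiles); d
      } else NULL
      h_act <- h_in <- NULL
      if (spec$hts_test) {
        h_act <- draw_from_families(pools, active_fams, n_hts_a, used)
        used <- c(used, h_act$smiles)
        h_in <- draw_from_families(pools, fam_names,
                                   spec$hts_ratio * n_hts_a, used)
        used <- c(used, h_in$smiles)
      }
      list(act = act, inact = rbind(inact_pure, inact_mix),
           h_act = h_act, h_in = h_in, used = used)
    }
    drawn <- tryCatch(draw_all(pools), error = function(e) {
      if (!grepl("capacity", conditionMessage(e))) stop(e)
      pools <<- build_pools(Inf)
      draw_all(pools)
    })
    act <- drawn$act; inact <- drawn$inact; used <- drawn$used
    ds <- labeled_dataset(c(act$smiles, inact$smiles),
                          rep(c("active", "inactive"),
                              c(nrow(act), nrow(inact))),
                          source = "synthetic")
    family <- c(act$family, inact$family)
    names(family) <- c(act$smiles, inact$smiles)

    hts <- NULL
    if (spec$hts_test) {
      hts <- labeled_dataset(c(drawn$h_act$smiles, drawn$h_in$smiles),
                             rep(c("active", "inactive"),
                                 c(nrow(drawn$h_act), nrow(drawn$h_in))),
                             source = "synthetic")
    }
    list(dataset = ds, hts_test = hts, family = family)
  })
}

#' Attach seeded bioactivity measurements to a synthetic dataset
#'
#' Produces raw bioactivity rows (the [read_bioactivities()] schema) that
#' exercise curation and cutoff scanning end-to-end: actives get log-uniform
#' values in `active_range_uM`, inactives in `inactive_range_uM` (a fifth of
#' them as censored "greater-than" records), and an `ambiguous_fraction` of
#' extra compounds receive values strictly between the two ranges. Units
#' alternate between micromolar and nanomolar to exercise conversion.
#'
#' @param spec a [synthetic_spec()].
#' @param active_range_uM,inactive_range_uM value ranges (micromolar).
#' @param ambiguous_fraction fraction (of the dataset size) of additional
#'   ambiguous-valued compounds.
#' @return data.frame in the raw bioactivity schema.
#' @export
generate_bioactivities <- function(spec, active_range_uM = c(0.01, 1),
                                   inactive_range_uM = c(10, 100),
                                   ambiguous_fraction = 0) {
  stopifnot(active_range_uM[1] < active_range_uM[2],
            inactive_range_uM[1] < inactive_range_uM[2],
            active_range_uM[2] <= inactive_range_uM[1],
            ambiguous_fraction >= 0, ambiguous_fraction < 1)
  gen <- generate_dataset(spec)
  ds <- gen$dataset
  n <- nrow(ds)
  with_seed(spec$seed + 1L, {
    lu <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
    value <- numeric(n); relation <- rep("=", n)
    ia <- ds$label == "active"
    value[ia] <- lu(sum(ia), active_range_uM)
    value[!ia] <- lu(sum(!ia), inactive_range_uM)
    cens <- which(!ia)[stats::runif(sum(!ia)) < 0.2]
    relation[cens] <- ">"
    value[cens] <- inactive_range_uM[1]
    df <- data.frame(compound_id = ds$compound_id, smiles = ds$canonical_smiles,
                     activity_type = rep(c("EC50", "IC50", "Ki"), length.out = n),
                     relation = relation, value = value, unit = "uM",
                     stringsAsFactors = FALSE)
    n_amb <- round(ambiguous_fraction * n)
    if (n_amb > 0) {
      spec2 <- spec; spec2$seed <- spec$seed + 7L
      spec2$n_active <- n_amb; spec2$n_inactive <- 1L; spec2$hts_test <- FALSE
      extra <- generate_dataset(spec2)$dataset
      extra <- extra[extra$label == "active", , drop = FALSE]
      extra <- extra[!extra$canonical_smiles %in% df$smiles, , drop = FALSE]
      m <- nrow(extra)
      amb_lo <- active_range_uM[2] * 1.01; amb_hi <- inactive_range_uM[1] * 0.99
      df <- rbind(df, data.frame(
        compound_id = paste0("amb", seq_len(m)), smiles = extra$canonical_smiles,
        activity_type = rep(c("EC50", "IC50", "Ki"), length.out = m),
        relation = "=", value = lu(m, c(amb_lo, amb_hi)), unit = "uM",
        stringsAsFactors = FALSE))
    }
    # half the rows restated in nanomolar (labels must be unit-invariant)
    half <- seq_len(nrow(df)) %% 2L == 0L
    df$value[half] <- df$value[half] * 1000
    df$unit[half] <- "nM"
    df
  })
}
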