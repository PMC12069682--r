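# Fingerprints, Tanimoto similarity, physicochemical descriptors.

#' Fingerprint configuration
#'
#' @param n_bits fingerprint length; a power of two, at least 64.
#' @param radius circular neighborhood bond radius (radius 2 corresponds to
#'   the ECFP4 convention).
#' @return an object of class `fp_config`.
#' @export
fp_config <- function(n_bits = 1024L, radius = 2L) {
  n_bits <- as.integer(n_bits); radius <- as.integer(radius)
  stopifnot(n_bits >= 64L, bitwAnd(n_bits, n_bits - 1L) == 0L, radius >= 1L)
  structure(list(n_bits = n_bits, radius = radius), class = "fp_config")
}

hex_to_bits <- function(hex_strings) {
  # FPS hex -> logical matrix (one row per molecule), nibble lookup table
  nib <- matrix(0L, 16, 4)
  for (i in 0:15) nib[i + 1, ] <- as.integer(bitwAnd(i, c(8L, 4L, 2L, 1L)) > 0)
  key <- c(0:9, letters[1:6]); names(key) <- c(as.character(0:9), letters[1:6])
  t(vapply(tolower(hex_strings), function(h) {
    idx <- match(strsplit(h, "", fixed = TRUE)[[1]], names(key))
    as.logical(t(nib[idx, , drop = FALSE]))
  }, logical(nchar(hex_strings[1]) * 4L), USE.NAMES = FALSE))
}

#' Circular (Morgan-style) fingerprints
#'
#' Hashed circular substructure fingerprints (extended-connectivity, ECFP
#' convention) computed with OpenBabel and folded by bitwise OR to the
#' requested length. Counts are collapsed to presence bits.
#'
#' @param smiles character vector of (ideally canonical) SMILES.
#' @param config a [fp_config()].
#' @param ids row identifiers; defaults to the SMILES strings.
#' @return a `fingerprint_matrix`: list with `ids`, a logical matrix `bits`
#'   (rows aligned with `ids`) and `config`.
#' @export
morgan_fingerprints <- function(smiles, config = fp_config(), ids = NULL) {
  stopifnot(inherits(config, "fp_config"))
  if (is.null(ids)) ids <- smiles
  stopifnot(length(ids) == length(smiles))
  if (!length(smiles)) {
    return(structure(list(ids = character(0),
                          bits = matrix(FALSE, 0, config$n_bits),
                          config = config), class = "fingerprint_matrix"))
  }
  fptype <- paste0("ECFP", 2L * config$radius)
  out <- ob_call(smiles, "fps", c(paste0("-xf", fptype)))
  body <- out[!startsWith(out, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  hexes <- vapply(parts, `[`, character(1), 1)
  got <- match(trimws(vapply(parts, `[`, character(1), 2)), attr(out, "ids"))
  if (anyNA(got) || length(got) != length(smiles)) {
    bad <- setdiff(seq_along(smiles), got)
    stop("fingerprinting failed for SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
  wide <- hex_to_bits(hexes)[order(got), , drop = FALSE]
  fold <- (seq_len(ncol(wide)) - 1L) %% config$n_bits
  bits <- matrix(FALSE, nrow(wide), config$n_bits)
  for (b in unique(fold)) {
    bits[, b + 1L] <- rowSums(wide[, fold == b, drop = FALSE]) > 0
  }
  structure(list(ids = as.character(ids), bits = bits, config = config),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d compounds x %d bits (radius %d)\n",
              nrow(x$bits), x$config$n_bits, x$config$radius))
  invisible(x)
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity between two fingerprint sets
#'
#' @param A,B logical matrices (rows = compounds) with equal bit length.
#' @return numeric matrix `nrow(A) x nrow(B)` of similarities.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  Am <- A * 1; Bm <- B * 1
  inter <- tcrossprod(Am, Bm)
  ca <- rowSums(Am); cb <- rowSums(Bm)
  uni <- outer(ca, cb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  sim
}

#' Export fingerprints as CSV
#'
#' Implementation-neutral format: one row per compound, columns `id` and
#' `bits` (the fingerprint as a 0/1 string).
#'
#' @param fps a `fingerprint_matrix`.
#' @param path output CSV path.
#' @export
write_fingerprints <- function(fps, path) {
  utils::write.csv(
    data.frame(id = fps$ids,
               bits = apply(fps$bits * 1, 1, paste, collapse = ""),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

# ring count from ring-closure tokens of a canonical SMILES: every ring
# closure digit (or %nn pair) appears twice and contributes one ring bond,
# and ring bonds = SSSR ring count for a connected molecule.
ring_count_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    s <- gsub("\\[[^]]*\\]", "A", s)  # bracket atoms carry no ring digits
    closures <- gregexpr("%[0-9]{2}|[0-9]", s)[[1]]
    n <- if (closures[1] == -1) 0L else length(closures)
    as.integer(n / 2)
  }, integer(1), USE.NAMES = FALSE)
}

#' Physicochemical descriptor profile
#'
#' Six descriptors used for class-distribution comparison: molecular weight,
#' logP, ring count, rotatable bonds, hydrogen-bond donors and acceptors.
#' Values other than ring count come from the OpenBabel descriptor engine.
#'
#' @param smiles character vector of canonical SMILES.
#' @return data.frame with columns `smiles`, `molecular_weight`, `logp`,
#'   `n_rings`, `n_rotatable_bonds`, `n_hbd`, `n_hba`.
#' @export
physchem_descriptors <- function(smiles) {
  stopifnot(length(smiles) > 0)
  out <- ob_call(smiles, "smi", c("--append", "MW logP rotors HBD HBA1"))
  # output fields: "SMILES\tid MW logP rotors HBD HBA1"
  tail_fields <- lapply(strsplit(out, "\t", fixed = TRUE), function(p) {
    strsplit(trimws(p[2]), "\\s+")[[1]]
  })
  got <- match(vapply(tail_fields, `[`, character(1), 1), attr(out, "ids"))
  if (anyNA(got) || length(got) != length(smiles)) {
    stop("descriptor computation failed for some SMILES")
  }
  vals <- do.call(rbind, lapply(tail_fields, function(f) {
    as.numeric(f[-1])
  }))[order(got), , drop = FALSE]
  data.frame(
    smiles = smiles,
    molecular_weight = vals[, 1],
    logp = vals[, 2],
    n_rings = ring_count_smiles(smiles),
    n_rotatable_bonds = as.integer(vals[, 3]),
    n_hbd = as.integer(vals[, 4]),
    n_hba = as.integer(vals[, 5]),
    stringsAsFactors = FALSE
  )
}
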