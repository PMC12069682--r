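# Low-level molecule handling through OpenBabel (`obabel` executable).
# All entry points are batch-oriented: one external call per vector of
# molecules, with synthetic ids used to detect per-molecule parse failures
# (obabel drops failed molecules from its output rather than erroring).

ob_binary <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop("OpenBabel ('obabel') was not found on PATH; it is required for ",
         "SMILES standardization and fingerprinting.", call. = FALSE)
  }
  path
}

#' Run obabel on a set of SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param out_format output format string (e.g. "can", "fps", "sdf").
#' @param extra_args additional obabel arguments.
#' @return character vector of output lines (molecules that failed to parse
#'   are silently absent; callers match survivors by title).
#' @keywords internal
ob_call <- function(smiles, out_format, extra_args = character()) {
  ids <- paste0("m", seq_along(smiles))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, ids), infile)
  # -e: continue with the next molecule after a parse error (failed
  # molecules are absent from the output and detected via their ids)
  out <- suppressWarnings(system2(
    ob_binary(),
    c("-ismi", infile, paste0("-o", out_format), "-e", extra_args),
    stdout = TRUE, stderr = FALSE
  ))
  attr(out, "ids") <- ids
  out
}

# Balanced-delimiter pre-check: obabel quietly truncates strings with
# unmatched open parentheses (e.g. "C(((" parses as methane), so catch
# those before handing anything to the parser.
smiles_syntax_ok <- function(s) {
  vapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(FALSE)
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    depth_p <- cumsum((chars == "(") - (chars == ")"))
    depth_b <- cumsum((chars == "[") - (chars == "]"))
    all(depth_p >= 0) && all(depth_b >= 0) &&
      depth_p[length(chars)] == 0 && depth_b[length(chars)] == 0 &&
      grepl("[A-Za-z*]", x)
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES in batch
#'
#' @param smiles character vector.
#' @param neutralize neutralize formal charges where chemically sensible.
#' @return character vector aligned with the input; NA where parsing failed.
#' @keywords internal
ob_canonical <- function(smiles, neutralize = FALSE) {
  res <- rep(NA_character_, length(smiles))
  ok <- smiles_syntax_ok(smiles)
  if (!any(ok)) return(res)
  extra <- if (neutralize) "--neutralize" else character()
  out <- ob_call(smiles[ok], "can", extra)
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    got_smi <- vapply(parts, `[`, character(1), 1)
    got_id <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)))
    idx <- match(got_id, attr(out, "ids"))
    keep <- !is.na(idx) & nzchar(got_smi)
    tmp <- rep(NA_character_, sum(ok))
    tmp[idx[keep]] <- got_smi[keep]
    res[ok] <- tmp
  }
  res
}

# SMILES tokenizer used by the generator vocabulary and by fragment size
# accounting. Two-character halogens Cl and Br are atomic tokens; everything
# else (including bracket-atom internals and % ring closures) stays
# character-split.
smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && chars[i] == "C" && chars[i + 1L] == "l") {
      toks <- c(toks, "Cl"); i <- i + 2L
    } else if (i < n && chars[i] == "B" && chars[i + 1L] == "r") {
      toks <- c(toks, "Br"); i <- i + 2L
    } else {
      toks <- c(toks, chars[i]); i <- i + 1L
    }
  }
  toks
}

# Heavy-atom and carbon counts per dot-separated fragment, from a regex scan
# of atom occurrences (bracket atoms count once; hydrogens excluded).
atom_pattern <- "\\[[^]]*\\]|Cl|Br|Si|Se|[BCNOPSFI]|[bcnops]"

count_heavy_atoms <- function(smiles) {
  m <- gregexpr(atom_pattern, smiles)[[1]]
  if (m[1] == -1) return(c(heavy = 0L, carbon = 0L))
  atoms <- regmatches(smiles, gregexpr(atom_pattern, smiles))[[1]]
  is_h <- grepl("^\\[[0-9]*[Hh][0-9+\\-]*\\]$", atoms)
  atoms <- atoms[!is_h]
  carbon <- grepl("^(C|c|\\[[0-9]*[Cc][^a-z].*\\]|\\[[0-9]*[Cc]\\])$", atoms) &
    !grepl("Cl", atoms, fixed = TRUE)
  c(heavy = length(atoms), carbon = sum(carbon))
}

# Keep the largest organic fragment of a (canonical) SMILES: most heavy
# atoms among carbon-containing fragments, falling back to all fragments
# when none contains carbon; first fragment wins ties.
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(smiles)
  counts <- t(vapply(frags, count_heavy_atoms, c(heavy = 0L, carbon = 0L)))
  cand <- which(counts[, "carbon"] > 0)
  if (!length(cand)) cand <- seq_along(frags)
  frags[cand[which.max(counts[cand, "heavy"])]]
}

#' Standardize raw SMILES strings
#'
#' Runs the standardization pipeline: parse, desalt by keeping the largest
#' organic fragment, neutralize formal charges where chemically valid, and
#' canonicalize. Identical molecules written as different raw strings map to
#' the same canonical string.
#'
#' @param raw character vector of raw SMILES.
#' @param source provenance tag recorded on each record, one of
#'   `"public"`, `"generated"`, `"synthetic"`.
#' @param compound_id optional ids (defaults to the raw strings).
#' @return data.frame with columns `compound_id`, `input`, `canonical_smiles`,
#'   `ok` (logical) and `reason` (`NA`, `"empty"` or `"parse_error"`);
#'   rejections are recorded, never fatal.
#' @export
#' @examples
#' \dontrun{
#' standardize_smiles(c("OCC", "CCO.Cl", "C((("))
#' }
standardize_smiles <- function(raw, source = "public", compound_id = NULL) {
  stopifnot(is.character(raw))
  source <- match.arg(source, c("public", "generated", "synthetic"))
  if (is.null(compound_id)) compound_id <- raw
  raw_t <- trimws(raw)
  res <- data.frame(
    compound_id = as.character(compound_id),
    input = raw,
    canonical_smiles = NA_character_,
    source = source,
    ok = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  empty <- !nzchar(raw_t) | is.na(raw_t)
  res$reason[empty] <- "empty"
  todo <- which(!empty)
  if (!length(todo)) return(res)

  # first pass: canonicalize the whole record (validity check)
  can1 <- ob_canonical(raw_t[todo])
  # desalt on the canonical form, then re-canonicalize with neutralization
  parsed <- which(!is.na(can1))
  if (length(parsed)) {
    frags <- vapply(can1[parsed], largest_organic_fragment, character(1),
                    USE.NAMES = FALSE)
    can2 <- ob_canonical(frags, neutralize = TRUE)
    keep <- !is.na(can2)
    rows <- todo[parsed][keep]
    res$canonical_smiles[rows] <- can2[keep]
    res$ok[rows] <- TRUE
  }
  res$reason[!res$ok & is.na(res$reason)] <- "parse_error"
  res
}
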