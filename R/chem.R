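# Thin chemistry layer over ChemmineOB (OpenBabel): SMILES parsing and
# canonicalization, InChIKey structure keys, circular fingerprints.
# Conversions run one molecule at a time so a single malformed SMILES can
# never shift the alignment of a batch; fingerprints are computed in one
# batch after invalid inputs have been rejected.

ob_convert1 <- function(smiles, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\tx\n")),
    error = function(e) "")
  out <- sub("\tx$", "", trimws(strsplit(out, "\n")[[1]][1]))
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Canonical SMILES
#'
#' Converts each SMILES to OpenBabel's canonical form, so that two spellings
#' of the same molecule compare equal. Unparsable inputs give `NA`.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES (`NA` where unparsable).
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), ob_convert1, character(1), to = "CAN",
         USE.NAMES = FALSE)
}

#' InChIKey structure keys from SMILES
#'
#' The full hashed InChIKey (all blocks, stereochemistry included) is the
#' deduplication identity for reference-library molecules: database exports
#' routinely spell one molecule as different SMILES, and stereoisomers must
#' stay distinct. Unparsable inputs give `NA`.
#'
#' @param smiles character vector.
#' @return character vector of InChIKeys (`NA` where unparsable).
#' @export
smiles_to_inchikey <- function(smiles) {
  vapply(as.character(smiles), ob_convert1, character(1), to = "INCHIKEY",
         USE.NAMES = FALSE)
}

fold_fp <- function(mat, bits) {
  n <- ncol(mat)
  if (bits >= n) return(mat != 0)
  groups <- (seq_len(n) - 1L) %% bits
  out <- matrix(FALSE, nrow(mat), bits)
  for (g in unique(groups))
    out[, g + 1L] <- out[, g + 1L] | (rowSums(mat[, groups == g, drop = FALSE]) > 0)
  rownames(out) <- rownames(mat)
  out
}

#' Circular (Morgan-type) fingerprints
#'
#' Computes OpenBabel ECFP4 fingerprints - circular atom-environment
#' fingerprints of radius 2, the standard choice for Tanimoto similarity
#' screening - and folds them to a fixed bit length (default 2048). The
#' fingerprint of a molecule is determined by its structure, not its SMILES
#' spelling.
#'
#' @param smiles character vector of SMILES.
#' @param bits fingerprint length after folding; the native ECFP4 length is
#'   4096, and `bits >= 4096` keeps it unfolded.
#' @param type OpenBabel fingerprint name (`"ECFP4"` default; `"FP2"` is a
#'   faster path-based alternative, 1024 bits native).
#' @return logical matrix, one row per input molecule (rownames = names of
#'   `smiles` if set, else the SMILES themselves).
#' @export
fingerprint <- function(smiles, bits = 2048L, type = "ECFP4") {
  ids <- names(smiles)
  smiles <- as.character(smiles)
  if (length(smiles) == 0L) stop("no SMILES given", call. = FALSE)
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("unparsable SMILES: ",
         paste(smiles[is.na(can)], collapse = ", "), call. = FALSE)
  if (is.null(ids)) ids <- smiles
  input <- paste0(smiles, "\tm", seq_along(smiles), "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  raw <- ChemmineOB::fingerprint_OB(mols, type)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  fp <- fold_fp(raw, as.integer(bits))
  rownames(fp) <- ids
  fp
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|a AND b| / |a OR b|`; 1 for identical non-empty fingerprints, 0 for
#' disjoint ones, and defined as 0 when both fingerprints are all-zero.
#'
#' @param a,b logical (or 0/1 numeric) vectors of equal length.
#' @return a number in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint length mismatch", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# All-pairs Tanimoto between fingerprint matrices (rows = molecules),
# via bit-count algebra: |A&B| = A %*% t(B), |A|B| = popA + popB - |A&B|.
tanimoto_matrix <- function(A, B) {
  An <- matrix(as.numeric(A), nrow(A))
  Bn <- matrix(as.numeric(B), nrow(B))
  inter <- An %*% t(Bn)
  un <- outer(rowSums(An), rowSums(Bn), "+") - inter
  res <- ifelse(un == 0, 0, inter / un)
  dimnames(res) <- list(rownames(A), rownames(B))
  res
}

#' Mean pairwise Tanimoto similarity of a set of molecules
#'
#' Used to judge the structural diversity of the ligands associated with one
#' target: values near 1 flag a single chemotype, low values (e.g. around
#' 0.2-0.3 for typical screening libraries) indicate no compound-class bias.
#'
#' @param smiles character vector of at least two SMILES.
#' @param bits,type fingerprint parameters, see [fingerprint()].
#' @return mean Tanimoto over all unordered pairs; `NA` (with a message)
#'   when fewer than two molecules are given.
#' @export
mean_pairwise_similarity <- function(smiles, bits = 2048L, type = "ECFP4") {
  smiles <- as.character(smiles)
  if (length(smiles) < 2L) {
    message("mean pairwise similarity undefined for <2 ligands")
    return(NA_real_)
  }
  fp <- fingerprint(smiles, bits = bits, type = type)
  tm <- tanimoto_matrix(fp, fp)
  mean(tm[upper.tri(tm)])
}
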