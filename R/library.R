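# Reference interaction libraries: loading database exports, merging them
# into a deduplicated union, and the ligand-based similarity screen.

#' Load a reference-interaction table
#'
#' Reads a delimited export of known target-ligand interactions (the shape
#' of a BindingDB or ChEMBL dump): one row per interaction, with a target
#' identifier and a ligand SMILES. When the table does not already carry a
#' structure key, the full InChIKey is computed from the SMILES; rows whose
#' SMILES cannot be parsed are dropped and counted.
#'
#' @param path delimited text file with columns `target_id` and `smiles`
#'   (tab or comma separated); optional columns `ligand_key` and `source`.
#' @param source_label name recorded for this source (defaults to the
#'   `source` column if present, else the file name).
#' @return data.frame with columns `target_id`, `ligand_key`, `smiles`,
#'   `source_label`; attribute `n_dropped` counts unparsable rows.
#' @export
load_interactions <- function(path, source_label = NULL) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  need <- c("target_id", "smiles")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(source_label))
    source_label <- if ("source" %in% names(df)) df$source[1]
      else if ("source_label" %in% names(df)) df$source_label[1]
      else basename(path)
  key <- if ("ligand_key" %in% names(df)) df$ligand_key else
    rep(NA_character_, nrow(df))
  key <- ifelse(is.na(key) | !nzchar(key), NA_character_, key)
  if (anyNA(key)) {
    missing_key <- is.na(key)
    key[missing_key] <- smiles_to_inchikey(df$smiles[missing_key])
  }
  ok <- !is.na(key) & nzchar(df$target_id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " row(s) with unparsable SMILES or empty target")
  if (!any(ok)) stop("no parsable interaction rows in ", path, call. = FALSE)
  out <- data.frame(target_id = df$target_id[ok],
                    ligand_key = key[ok],
                    smiles = df$smiles[ok],
                    source_label = source_label,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("target_id", "ligand_key")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Merge reference-interaction sources into one deduplicated library
#'
#' The union is keyed on (target id, ligand structure key): an interaction
#' present in several sources counts once. Per-source sizes, all pairwise
#' overlaps and the union size are recorded, so the merge arithmetic
#' |A| + |B| - |A AND B| = |A OR B| is directly inspectable.
#'
#' @param sets list of interaction data.frames as returned by
#'   [load_interactions()] (or a single one).
#' @return data.frame of class `reference_library` with the union of
#'   interactions; attributes `merge_stats` (list: `source_sizes`,
#'   `overlaps` matrix, `union_size`) and `target_counts` (ligands per
#'   target).
#' @export
merge_libraries <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) < 1L) stop("need at least one source", call. = FALSE)
  keys <- lapply(sets, function(s) paste(s$target_id, s$ligand_key, sep = "\r"))
  labels <- vapply(seq_along(sets), function(i) {
    lab <- unique(sets[[i]]$source_label)
    if (length(lab) == 1L) lab else paste0("source", i)
  }, character(1))
  sizes <- vapply(keys, function(k) length(unique(k)), integer(1))
  names(sizes) <- labels
  n <- length(sets)
  ov <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n))
    ov[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  all <- do.call(rbind, sets)
  lib <- all[!duplicated(paste(all$target_id, all$ligand_key, sep = "\r")), ,
             drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("reference_library", "data.frame")
  attr(lib, "merge_stats") <- list(source_sizes = sizes, overlaps = ov,
                                   union_size = nrow(lib))
  attr(lib, "target_counts") <- table(lib$target_id)
  lib
}

#' @export
print.reference_library <- function(x, ...) {
  st <- attr(x, "merge_stats")
  cat(sprintf("reference_library: %d unique interactions, %d targets\n",
              nrow(x), length(unique(x$target_id))))
  if (!is.null(st)) {
    cat("  sources:", paste(sprintf("%s=%d", names(st$source_sizes),
                                    st$source_sizes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ligand-based similarity screen against a reference library
#'
#' For every query compound and every target, the maximum Tanimoto
#' similarity between the query and the target's reference ligands is
#' computed; when it reaches the cutoff (inclusive; default 0.75, chosen to
#' be less restrictive than the common 0.85) the query is considered a
#' potential ligand of that target. Each (query, target) pair yields at most
#' one hit, recording the best-matching reference ligand; a query may hit
#' many targets.
#'
#' @param queries data.frame with columns `compound_id` and `smiles`.
#' @param lib a [merge_libraries()] result (or any data.frame with
#'   `target_id`, `ligand_key`, `smiles`).
#' @param cutoff similarity threshold in (0, 1].
#' @param bits,type fingerprint parameters, see [fingerprint()].
#' @return data.frame of class `similarity_hits` with columns `compound_id`,
#'   `target_id`, `tanimoto`, `best_reference_key`.
#' @export
screen_library <- function(queries, lib, cutoff = 0.75, bits = 2048L,
                           type = "ECFP4") {
  stopifnot(is.data.frame(queries),
            all(c("compound_id", "smiles") %in% names(queries)))
  if (cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must be in (0, 1]", call. = FALSE)
  empty <- data.frame(compound_id = character(), target_id = character(),
                      tanimoto = numeric(), best_reference_key = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("similarity_hits", "data.frame")
  if (nrow(lib) == 0L) {
    warning("empty reference library: no hits", call. = FALSE)
    return(empty)
  }
  qcan <- canonical_smiles(queries$smiles)
  bad <- is.na(qcan)
  if (any(bad)) {
    warning("dropping ", sum(bad), " query compound(s) with unparsable SMILES",
            call. = FALSE)
    queries <- queries[!bad, , drop = FALSE]
  }
  if (nrow(queries) == 0L) return(empty)
  qfp <- fingerprint(stats::setNames(queries$smiles, queries$compound_id),
                     bits = bits, type = type)
  # fingerprint each distinct reference molecule once
  refs <- lib[!duplicated(lib$ligand_key), c("ligand_key", "smiles")]
  rcan <- canonical_smiles(refs$smiles)
  refs <- refs[!is.na(rcan), , drop = FALSE]
  if (nrow(refs) == 0L) {
    warning("no parsable reference SMILES: no hits", call. = FALSE)
    return(empty)
  }
  rfp <- fingerprint(stats::setNames(refs$smiles, refs$ligand_key),
                     bits = bits, type = type)
  sim <- tanimoto_matrix(qfp, rfp)  # queries x reference molecules
  hits <- lapply(split(lib$ligand_key, lib$target_id), function(keys) {
    sub <- sim[, intersect(colnames(sim), unique(keys)), drop = FALSE]
    if (ncol(sub) == 0L) return(NULL)
    best <- apply(sub, 1L, max)
    sel <- which(best >= cutoff)
    if (length(sel) == 0L) return(NULL)
    bk <- colnames(sub)[apply(sub[sel, , drop = FALSE], 1L, which.max)]
    data.frame(compound_id = rownames(sub)[sel], tanimoto = best[sel],
               best_reference_key = bk, stringsAsFactors = FALSE)
  })
  keep <- !vapply(hits, is.null, logical(1))
  if (!any(keep)) return(empty)
  out <- do.call(rbind, Map(function(h, t) {
    h$target_id <- t
    h
  }, hits[keep], names(hits)[keep]))
  out <- out[, c("compound_id", "target_id", "tanimoto", "best_reference_key")]
  out <- out[order(out$target_id, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("similarity_hits", "data.frame")
  out
}

#' Write similarity hits as tab-delimited text
#' @param hits a `similarity_hits` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
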