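#' Docking score matrix
#'
#' A `score_matrix` holds the binding energies (kcal/mol) from one inverse
#' docking campaign: one row per query ligand, one column per protein target,
#' produced by a single docking program. More negative values mean stronger
#' predicted binding. Cells may be missing (`NA`) where a docking failed or
#' was masked during validation; missing cells are excluded from every mean
#' and standard deviation downstream and can never yield a pairing.
#'
#' @param scores numeric matrix with ligand ids as rownames and target ids as
#'   colnames. Dimnames are mandatory and must be unique within each axis.
#' @param program_label free-text name of the docking program that produced
#'   the matrix (e.g. `"smina"`). Matrices from different programs are never
#'   merged numerically; each flows through post-processing on its own.
#' @return An object of class `score_matrix`.
#' @seealso [read_score_matrix()], [validate_scores()], [exclude_targets()]
#' @export
score_matrix <- function(scores, program_label = "docking") {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` must carry ligand rownames and target colnames", call. = FALSE)
  if (nrow(scores) == 0L || ncol(scores) == 0L)
    stop("empty score matrix", call. = FALSE)
  if (anyDuplicated(rownames(scores)))
    stop("duplicate ligand identifiers", call. = FALSE)
  if (anyDuplicated(colnames(scores)))
    stop("duplicate target identifiers", call. = FALSE)
  structure(
    list(scores = scores,
         program_label = as.character(program_label)[1],
         validated = FALSE,
         log = character()),
    class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d ligands x %d targets [%s]%s\n",
              nrow(x$scores), ncol(x$scores), x$program_label,
              if (x$validated) ", validated" else ""))
  cat(sprintf("  defined cells: %d of %d\n",
              sum(!is.na(x$scores)), length(x$scores)))
  if (length(x$log)) cat("  log:", length(x$log), "entries\n")
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' Ligand and target identifiers of a score matrix
#' @param m a `score_matrix`
#' @return character vector of identifiers, in matrix order.
#' @export
ligand_ids <- function(m) rownames(m$scores)

#' @rdname ligand_ids
#' @export
target_ids <- function(m) colnames(m$scores)

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty table: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a score matrix from a delimited text file
#'
#' The expected layout is a header row naming the targets, a first column
#' (`ligand_id`) naming the ligands, and binding energies in kcal/mol in the
#' body. Comma and tab delimiters are auto-detected; non-numeric or empty
#' cells are recorded as missing.
#'
#' @inheritParams score_matrix
#' @param path path to the delimited file.
#' @return A `score_matrix` (not yet validated; see [validate_scores()]).
#' @export
read_score_matrix <- function(path, program_label = "docking") {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed score table: ", path, call. = FALSE)
  lig <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  dimnames(storage) <- list(lig, colnames(df)[-1])
  score_matrix(storage, program_label)
}

#' Write a score matrix as tab-delimited text
#'
#' Output round-trips bit-identically through [read_score_matrix()] for
#' finite matrices. Missing cells are written empty.
#'
#' @param m a `score_matrix`
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  df <- data.frame(ligand_id = ligand_ids(m), m$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a score matrix for post-processing
#'
#' Docking energies are kept on the negative scale (more negative = stronger
#' binding). Cells with a non-negative value are invalid binders - a
#' mixed-sign matrix would make the quotient normalization non-monotone - so
#' they are masked as missing and counted in the run log. A ligand row or
#' target column left entirely missing is dropped with a warning.
#'
#' @param m a `score_matrix`
#' @return The validated `score_matrix`; `m$log` records masked cells and
#'   dropped rows/columns.
#' @export
validate_scores <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  s <- m$scores
  bad <- !is.na(s) & s >= 0
  if (any(bad)) {
    s[bad] <- NA_real_
    m$log <- c(m$log, sprintf("masked %d non-negative cell(s)", sum(bad)))
  }
  empty_row <- rowSums(!is.na(s)) == 0L
  empty_col <- colSums(!is.na(s)) == 0L
  if (any(empty_row)) {
    warning("dropping ligand row(s) with no defined score: ",
            paste(rownames(s)[empty_row], collapse = ", "), call. = FALSE)
    m$log <- c(m$log, sprintf("dropped %d empty ligand row(s): %s",
                              sum(empty_row),
                              paste(rownames(s)[empty_row], collapse = ",")))
    s <- s[!empty_row, , drop = FALSE]
  }
  if (any(empty_col)) {
    warning("dropping target column(s) with no defined score: ",
            paste(colnames(s)[empty_col], collapse = ", "), call. = FALSE)
    m$log <- c(m$log, sprintf("dropped %d empty target column(s): %s",
                              sum(empty_col),
                              paste(colnames(s)[empty_col], collapse = ",")))
    s <- s[, !empty_col, drop = FALSE]
  }
  if (nrow(s) == 0L || ncol(s) == 0L)
    stop("no defined scores left after validation", call. = FALSE)
  m$scores <- s
  m$validated <- TRUE
  m
}

#' Remove promiscuous targets from a score matrix
#'
#' Both post-processing methods lean on per-ligand averages across all
#' targets, so a target that attracts anomalously many strong scores (e.g. a
#' promiscuous kinase) biases the statistics matrix-wide. Removing such
#' targets and re-running the analysis is the standard counter-measure; see
#' [detect_promiscuous()] for choosing the exclusion list.
#'
#' @param m a `score_matrix`
#' @param exclusion character vector of target ids to drop. Unknown ids are
#'   ignored with a warning.
#' @return A new `score_matrix` without the named target columns.
#' @export
exclude_targets <- function(m, exclusion) {
  stopifnot(inherits(m, "score_matrix"))
  exclusion <- as.character(exclusion)
  if (length(exclusion) == 0L) return(m)
  unknown <- setdiff(exclusion, target_ids(m))
  if (length(unknown))
    warning("ignoring unknown target id(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- setdiff(target_ids(m), exclusion)
  if (length(keep) == 0L)
    stop("exclusion would remove all targets", call. = FALSE)
  dropped <- intersect(exclusion, target_ids(m))
  m$scores <- m$scores[, keep, drop = FALSE]
  if (length(dropped))
    m$log <- c(m$log, sprintf("excluded target(s): %s",
                              paste(dropped, collapse = ",")))
  m
}
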