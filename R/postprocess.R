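# Post-processing of inverse-docking score matrices.
#
# Two independent statistical treatments of the same ligand x target energy
# matrix:
#   method I  - quotient normalization V = V0 / ((ML + MT) / 2) followed by
#               selection of cells with V >= M + 3*sigma;
#   method II - two-directional Z-transformation, Zcomb = wT*ZT + wL*ZL
#               (defaults 0.7 / 0.3), then the lowest Zcomb per ligand names
#               its most likely target.
# All standard deviations are population SDs (divide by n), so the
# matrix-wide sigma and the axis SDs are on the same convention.

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Quotient normalization of a docking score matrix (method I)
#'
#' Each binding energy `V0` is replaced by
#' `V = V0 / ((ML + MT) / 2)` where `ML` is the mean energy of the cell's
#' ligand row and `MT` the mean of its target column (defined cells only).
#' With an all-negative matrix the quotient is positive and larger values
#' mean relatively stronger binding; ligand- and target-wide systematic
#' shifts largely cancel. The normalized matrix additionally carries its
#' grand mean `M`, population standard deviation `sigma`, and the selection
#' threshold `M + 3*sigma`.
#'
#' @param m a validated [score_matrix()] (all defined cells strictly
#'   negative; see [validate_scores()]).
#' @return An object of class `normalized_matrix` with elements `values`,
#'   `matrix_mean`, `matrix_sd`, `threshold`, `program_label`, `log`.
#' @export
normalize_method1 <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  s <- m$scores
  if (any(s >= 0, na.rm = TRUE))
    stop("matrix contains non-negative cells; run validate_scores() first",
         call. = FALSE)
  ML <- rowMeans(s, na.rm = TRUE)
  MT <- colMeans(s, na.rm = TRUE)
  denom <- outer(ML, MT, "+") / 2
  V <- s / denom
  M <- mean(V, na.rm = TRUE)
  sigma <- pop_sd(V)
  structure(
    list(values = V, matrix_mean = M, matrix_sd = sigma,
         threshold = M + 3 * sigma,
         program_label = m$program_label, log = m$log),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix [%s]: %d x %d, M = %.4f, sigma = %.4f, threshold = %.4f\n",
              x$program_label, nrow(x$values), ncol(x$values),
              x$matrix_mean, x$matrix_sd, x$threshold))
  invisible(x)
}

#' Target-ligand pairing set
#'
#' The atomic evidence unit for consensus scoring: the pairings selected by
#' one post-processing method, on one program's matrix, in one run (with all
#' targets, or after excluding promiscuous ones).
#'
#' @param target_id,ligand_id character vectors of equal length.
#' @param method `"method1"`, `"method2"` or `"similarity"`.
#' @param program docking program label; empty for ligand-based evidence.
#' @param run `"all_targets"` or `"excl_promiscuous"`.
#' @return data.frame of class `pairing_set` with columns `target_id`,
#'   `ligand_id`, `method`, `program`, `run`; pairs are unique.
#' @export
pairing_set <- function(target_id, ligand_id, method, program = "",
                        run = "all_targets") {
  if (length(target_id) == 0L) {
    method <- character(); program <- character(); run <- character()
  }
  df <- data.frame(target_id = as.character(target_id),
                   ligand_id = as.character(ligand_id),
                   method = method, program = program, run = run,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("target_id", "ligand_id")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pairing_set", "data.frame")
  df
}

#' Select high-ranking pairings above the three-sigma threshold (method I)
#'
#' Returns every (target, ligand) cell whose normalized value reaches
#' `M + 3*sigma`. The comparison is inclusive: the threshold names the
#' boundary as admissible, so on a degenerate constant matrix (sigma = 0)
#' every defined cell equals `M` and all pass; this is logged.
#'
#' @param nm a `normalized_matrix` from [normalize_method1()].
#' @param run run label carried into the returned set.
#' @return A [pairing_set()] with `method = "method1"`.
#' @export
threshold_method1 <- function(nm, run = "all_targets") {
  stopifnot(inherits(nm, "normalized_matrix"))
  sel <- which(!is.na(nm$values) & nm$values >= nm$threshold, arr.ind = TRUE)
  if (!is.na(nm$matrix_sd) && nm$matrix_sd == 0)
    message("degenerate normalized matrix (sigma = 0): all defined cells pass")
  pairing_set(target_id = colnames(nm$values)[sel[, 2]],
              ligand_id = rownames(nm$values)[sel[, 1]],
              method = "method1", program = nm$program_label, run = run)
}

standardize <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- pop_sd(x)
  if (is.na(s) || s == 0) {
    z <- x
    z[!is.na(z)] <- 0
    return(z)
  }
  (x - mu) / s
}

#' Two-directional Z-transformation of a docking score matrix (method II)
#'
#' Standardizes every cell along both axes of the matrix: `ZT` within its
#' ligand row (across targets), correcting ligand-specific score shifts, and
#' `ZL` within its target column (across ligands), correcting target-specific
#' shifts. The combined score is `Zcomb = wT*ZT + wL*ZL` with default weights
#' 0.7 / 0.3. Rows or columns with fewer than two defined cells are dropped
#' with a warning; an axis with zero standard deviation gets Z = 0 for all
#' its cells (logged).
#'
#' The axis assignment of the two Z-scores is configurable: with
#' `orientation = "swapped"` ZT standardizes columns and ZL rows instead.
#'
#' @param m a validated [score_matrix()].
#' @param weights numeric length-2 vector `c(target = wT, ligand = wL)`
#'   summing to 1.
#' @param orientation `"across_targets"` (default: ZT row-wise, ZL
#'   column-wise) or `"swapped"`.
#' @return An object of class `zmatrices` with elements `ZT`, `ZL`, `Zcomb`,
#'   `weights`, `program_label`, `log`.
#' @export
ztransform_2d <- function(m, weights = c(target = 0.7, ligand = 0.3),
                          orientation = c("across_targets", "swapped")) {
  stopifnot(inherits(m, "score_matrix"))
  orientation <- match.arg(orientation)
  if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-12)
    stop("`weights` must be two values summing to 1", call. = FALSE)
  s <- m$scores
  log <- m$log
  keep_r <- rowSums(!is.na(s)) >= 2L
  keep_c <- colSums(!is.na(s)) >= 2L
  if (!all(keep_r)) {
    warning("dropping ligand row(s) with <2 defined cells: ",
            paste(rownames(s)[!keep_r], collapse = ", "), call. = FALSE)
    log <- c(log, sprintf("ztransform: dropped %d row(s)", sum(!keep_r)))
  }
  if (!all(keep_c)) {
    warning("dropping target column(s) with <2 defined cells: ",
            paste(colnames(s)[!keep_c], collapse = ", "), call. = FALSE)
    log <- c(log, sprintf("ztransform: dropped %d column(s)", sum(!keep_c)))
  }
  s <- s[keep_r, keep_c, drop = FALSE]
  if (nrow(s) < 2L || ncol(s) < 2L)
    stop("matrix too small for two-directional Z-transformation", call. = FALSE)
  by_row <- t(apply(s, 1L, standardize))
  by_col <- apply(s, 2L, standardize)
  dimnames(by_row) <- dimnames(s)
  dimnames(by_col) <- dimnames(s)
  if (orientation == "across_targets") {
    ZT <- by_row; ZL <- by_col
  } else {
    ZT <- by_col; ZL <- by_row
  }
  if (any(apply(s, 1L, pop_sd) == 0, na.rm = TRUE) ||
      any(apply(s, 2L, pop_sd) == 0, na.rm = TRUE))
    log <- c(log, "ztransform: zero-SD axis encountered, Z set to 0")
  structure(
    list(ZT = ZT, ZL = ZL,
         Zcomb = weights[[1]] * ZT + weights[[2]] * ZL,
         weights = weights, program_label = m$program_label, log = log),
    class = "zmatrices")
}

#' Select the most likely target per ligand (method II)
#'
#' For every ligand the target with the lowest combined Z-score is selected
#' (most negative = strongest relative binding). Exact ties are broken by
#' lexicographic target-id order and logged; ligands without any defined
#' Zcomb are omitted with a message. There is no score cutoff by default - a
#' ligand always yields exactly one pairing if any Zcomb is defined - but an
#' optional upper `cutoff` on Zcomb can be supplied.
#'
#' @param z a `zmatrices` object from [ztransform_2d()].
#' @param cutoff optional numeric; keep only selections with
#'   `Zcomb <= cutoff`.
#' @param run run label carried into the returned set.
#' @return A [pairing_set()] with `method = "method2"`, at most one row per
#'   ligand.
#' @export
select_best_targets <- function(z, cutoff = NULL, run = "all_targets") {
  stopifnot(inherits(z, "zmatrices"))
  Z <- z$Zcomb
  tid <- colnames(Z)
  ord <- order(tid)  # lexicographic tie-break
  picks <- vapply(seq_len(nrow(Z)), function(i) {
    row <- Z[i, ord]
    if (all(is.na(row))) return(NA_character_)
    j <- which(row == min(row, na.rm = TRUE))[1]
    tid[ord][j]
  }, character(1))
  omitted <- is.na(picks)
  if (any(omitted))
    message("omitting ", sum(omitted), " ligand(s) with no defined Zcomb")
  sel_l <- rownames(Z)[!omitted]
  sel_t <- picks[!omitted]
  if (!is.null(cutoff)) {
    val <- Z[cbind(match(sel_l, rownames(Z)), match(sel_t, colnames(Z)))]
    keep <- val <= cutoff
    sel_l <- sel_l[keep]; sel_t <- sel_t[keep]
  }
  pairing_set(target_id = sel_t, ligand_id = sel_l,
              method = "method2", program = z$program_label, run = run)
}

#' Run one post-processing method end to end
#'
#' Dispatches to [normalize_method1()] + [threshold_method1()] or to
#' [ztransform_2d()] + [select_best_targets()], attaching method, program
#' and run labels to the resulting pairing set.
#'
#' @param m a validated [score_matrix()].
#' @param method `"method1"` or `"method2"`.
#' @param run run label (`"all_targets"` or `"excl_promiscuous"`).
#' @param weights,orientation,cutoff passed to the method-II steps.
#' @return A [pairing_set()].
#' @export
run_method <- function(m, method = c("method1", "method2"),
                       run = "all_targets",
                       weights = c(target = 0.7, ligand = 0.3),
                       orientation = "across_targets", cutoff = NULL) {
  method <- match.arg(method)
  if (method == "method1") {
    threshold_method1(normalize_method1(m), run = run)
  } else {
    select_best_targets(ztransform_2d(m, weights = weights,
                                      orientation = orientation),
                        cutoff = cutoff, run = run)
  }
}

#' Write a pairing set as tab-delimited text
#' @param p a [pairing_set()]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairings <- function(p, path) {
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a normalized or Z matrix in the score-matrix format
#' @param x a `normalized_matrix` or `zmatrices` object.
#' @param path output file path.
#' @param which for `zmatrices`: `"Zcomb"`, `"ZT"` or `"ZL"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, which = "Zcomb") {
  v <- if (inherits(x, "normalized_matrix")) x$values else x[[which]]
  df <- data.frame(ligand_id = rownames(v), v,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
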