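# Consensus scoring across evidence channels.
#
# The approach universe has five members: each post-processing method on
# each docking program's matrix (four target-based channels) plus the
# ligand-based similarity screen. A pairing's confidence score is the number
# of distinct approaches that identified it - between 1 and 5 - regardless
# of how many runs (with or without promiscuous-target exclusion) an
# approach fired in.

approach_of <- function(method, program) {
  ifelse(method == "similarity", "similarity",
         paste(method, program, sep = ":"))
}

#' Fuse pairing sets and similarity hits into a consensus table
#'
#' Pairings are unified on (target, ligand). An approach supports a pairing
#' if it identified it in any run; by default each approach counts once, so
#' the confidence score is the number of distinct supporting approaches
#' (`count_runs = TRUE` switches to approach-by-run counting). Duplicate
#' (method, program, run) inputs are rejected to guard against accidental
#' double counting.
#'
#' @param pairing_sets list of [pairing_set()] objects from the target-based
#'   post-processing runs.
#' @param hits optional `similarity_hits` data.frame from
#'   [screen_library()]; counts as the single ligand-based approach.
#' @param count_runs count each (approach, run) combination separately
#'   instead of each approach once.
#' @return data.frame of class `consensus_table` with columns `target_id`,
#'   `ligand_id`, `confidence`, `approaches` (semicolon-joined), `runs`
#'   (semicolon-joined).
#' @export
build_consensus <- function(pairing_sets = list(), hits = NULL,
                            count_runs = FALSE) {
  if (inherits(pairing_sets, "pairing_set")) pairing_sets <- list(pairing_sets)
  chan <- vapply(pairing_sets, function(p)
    paste(unique(p$method), unique(p$program), unique(p$run), collapse = "|"),
    character(1))
  if (anyDuplicated(chan))
    stop("duplicate (method, program, run) pairing sets supplied", call. = FALSE)
  rows <- lapply(pairing_sets, function(p)
    data.frame(target_id = p$target_id, ligand_id = p$ligand_id,
               approach = approach_of(p$method, p$program), run = p$run,
               stringsAsFactors = FALSE))
  if (!is.null(hits) && nrow(hits) > 0L)
    rows <- c(rows, list(data.frame(target_id = hits$target_id,
                                    ligand_id = hits$compound_id,
                                    approach = "similarity",
                                    run = "all_targets",
                                    stringsAsFactors = FALSE)))
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), ligand_id = character(),
               approach = character(), run = character(),
               stringsAsFactors = FALSE)
  key <- paste(ev$target_id, ev$ligand_id, sep = "\r")
  unit <- if (count_runs) paste(ev$approach, ev$run, sep = "@") else ev$approach
  sp_unit <- split(unit, key)
  sp_run <- split(ev$run, key)
  uk <- names(sp_unit)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(
    target_id = vapply(parts, `[`, character(1), 1L),
    ligand_id = vapply(parts, `[`, character(1), 2L),
    confidence = vapply(sp_unit, function(u) length(unique(u)), integer(1)),
    approaches = vapply(sp_unit, function(u)
      paste(sort(unique(u)), collapse = ";"), character(1)),
    runs = vapply(sp_run, function(r)
      paste(sort(unique(r)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$target_id, out$ligand_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table: %d unique target-ligand pairings\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(factor(x$confidence, levels = sort(unique(x$confidence),
                                                    decreasing = TRUE)))
    cat("  confidence:", paste(sprintf("%s:%d", names(tab), tab),
                               collapse = "  "), "\n")
  }
  invisible(x)
}

#' Summaries of a consensus table
#'
#' @param t a `consensus_table` from [build_consensus()].
#' @return list with elements:
#'   `score_counts` (pairings per confidence score 1-5),
#'   `ligands_per_target` (named integer vector, decreasing),
#'   `targets_per_ligand` (histogram: number of ligands having k targets),
#'   `family_overlap` (structure-based vs ligand-based pairing counts and
#'   their intersection/union).
#' @export
summarize_consensus <- function(t) {
  stopifnot(inherits(t, "consensus_table"))
  score_counts <- integer(5)
  names(score_counts) <- as.character(1:5)
  if (nrow(t)) {
    tt <- table(t$confidence)
    score_counts[names(tt)] <- as.integer(tt)
  }
  lig_per_tar <- if (nrow(t))
    sort(table(t$target_id), decreasing = TRUE) else table(character())
  tar_per_lig <- if (nrow(t)) table(table(t$ligand_id)) else table(integer())
  has_sim <- grepl("(^|;)similarity($|;)", t$approaches)
  has_struct <- vapply(strsplit(t$approaches, ";"), function(a)
    any(a != "similarity"), logical(1))
  family_overlap <- c(structure_based = sum(has_struct),
                      ligand_based = sum(has_sim),
                      both = sum(has_sim & has_struct),
                      union = nrow(t))
  list(score_counts = score_counts,
       ligands_per_target = lig_per_tar,
       targets_per_ligand = tar_per_lig,
       family_overlap = family_overlap)
}

#' Flag promiscuous targets
#'
#' A promiscuous target (typically a kinase) attracts anomalously many
#' predicted ligands and, because both post-processing methods use
#' per-ligand averages over all targets, biases the whole analysis; the
#' remedy is to exclude it from the score matrices and re-run. The default
#' policy simply passes through a manually curated exclusion list; the
#' automatic policy flags targets whose ligand count exceeds
#' `median + k * MAD` (unscaled median absolute deviation, `k = 5`) of the
#' per-target counts pooled over all supplied pairing sets.
#'
#' @param pairing_sets list of [pairing_set()] objects.
#' @param policy `"manual"` or `"mad"`.
#' @param manual character vector of target ids (manual policy).
#' @param k MAD multiplier for the automatic policy.
#' @return character vector of flagged target ids.
#' @export
detect_promiscuous <- function(pairing_sets, policy = c("manual", "mad"),
                               manual = character(), k = 5) {
  policy <- match.arg(policy)
  if (policy == "manual") return(as.character(manual))
  if (inherits(pairing_sets, "pairing_set")) pairing_sets <- list(pairing_sets)
  ev <- do.call(rbind, lapply(pairing_sets, function(p)
    p[, c("target_id", "ligand_id")]))
  if (is.null(ev) || nrow(ev) == 0L) return(character())
  counts <- vapply(split(ev$ligand_id, ev$target_id), function(l)
    length(unique(l)), integer(1))
  med <- stats::median(counts)
  dev <- stats::median(abs(counts - med))
  flagged <- names(counts)[counts > med + k * dev]
  if (length(flagged))
    message("flagged promiscuous target(s): ",
            paste(sprintf("%s (%d ligands)", flagged, counts[flagged]),
                  collapse = ", "),
            " [median ", med, ", MAD ", dev, "]")
  sort(flagged)
}

#' Write a consensus table as tab-delimited text
#' @param t a `consensus_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
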