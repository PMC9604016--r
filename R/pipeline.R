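# End-to-end orchestration: validate each program's score matrix, run both
# post-processing methods per program (with and, if requested, without
# promiscuous targets), run the similarity screen, fuse everything into the
# consensus table and project the network.

#' Screening configuration
#'
#' Captures every tunable of the pipeline in one list. Defaults follow the
#' method: Tanimoto cutoff 0.75 (inclusive), circular ECFP4 fingerprints
#' folded to 2048 bits, Zcomb weights 0.7/0.3 with ZT across targets,
#' inclusive 3-sigma threshold, no Zcomb cutoff, manual promiscuity policy.
#'
#' @param tanimoto_cutoff similarity threshold in (0, 1].
#' @param fp_bits,fp_type fingerprint parameters (see [fingerprint()]).
#' @param z_weights length-2 vector `c(target, ligand)` summing to 1.
#' @param z_orientation `"across_targets"` or `"swapped"`.
#' @param zcomb_cutoff optional upper cutoff on Zcomb selections.
#' @param exclusion character vector of promiscuous target ids to exclude
#'   in the re-run (empty = no exclusion run).
#' @param promiscuity_policy,promiscuity_k see [detect_promiscuous()].
#' @param count_runs see [build_consensus()].
#' @return list of class `screening_config`.
#' @export
screening_config <- function(tanimoto_cutoff = 0.75, fp_bits = 2048L,
                             fp_type = "ECFP4",
                             z_weights = c(target = 0.7, ligand = 0.3),
                             z_orientation = "across_targets",
                             zcomb_cutoff = NULL,
                             exclusion = character(),
                             promiscuity_policy = "manual",
                             promiscuity_k = 5,
                             count_runs = FALSE) {
  structure(list(tanimoto_cutoff = tanimoto_cutoff,
                 fp_bits = as.integer(fp_bits), fp_type = fp_type,
                 z_weights = z_weights, z_orientation = z_orientation,
                 zcomb_cutoff = zcomb_cutoff, exclusion = exclusion,
                 promiscuity_policy = promiscuity_policy,
                 promiscuity_k = promiscuity_k,
                 count_runs = count_runs),
            class = "screening_config")
}

#' Read a screening configuration from a YAML file
#'
#' Keys match the arguments of [screening_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a `screening_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read configuration files",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(screening_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(screening_config, vals[intersect(names(vals), known)])
}

#' Run the full dual inverse-screening analysis
#'
#' For each docking program's matrix: validate, then run method I and
#' method II (run label `all_targets`); if an exclusion list is configured,
#' drop those targets and repeat both methods (run label
#' `excl_promiscuous`). If queries and a reference library are given, run
#' the similarity screen (unaffected by the exclusion, which only concerns
#' the docking statistics). All evidence is fused into the consensus table
#' and projected onto the protein-ligand interaction network.
#'
#' @param matrices named list of [score_matrix()] objects, one per docking
#'   program (names are used as program labels if the matrices carry none).
#' @param queries optional query compound data.frame (`compound_id`,
#'   `smiles`).
#' @param library optional [merge_libraries()] result.
#' @param config a [screening_config()].
#' @return list with `pairing_sets`, `hits`, `consensus`, `summary`,
#'   `network`, `exclusion`.
#' @export
run_inverse_screen <- function(matrices, queries = NULL, library = NULL,
                               config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  if (inherits(matrices, "score_matrix")) matrices <- list(matrices)
  matrices <- lapply(matrices, validate_scores)
  pairing_sets <- list()
  for (m in matrices) {
    for (meth in c("method1", "method2")) {
      pairing_sets <- c(pairing_sets, list(
        run_method(m, meth, run = "all_targets",
                   weights = config$z_weights,
                   orientation = config$z_orientation,
                   cutoff = config$zcomb_cutoff)))
    }
  }
  exclusion <- as.character(config$exclusion)
  if (config$promiscuity_policy == "mad")
    exclusion <- detect_promiscuous(pairing_sets, policy = "mad",
                                    k = config$promiscuity_k)
  if (length(exclusion)) {
    for (m in matrices) {
      mx <- exclude_targets(m, exclusion)
      for (meth in c("method1", "method2")) {
        pairing_sets <- c(pairing_sets, list(
          run_method(mx, meth, run = "excl_promiscuous",
                     weights = config$z_weights,
                     orientation = config$z_orientation,
                     cutoff = config$zcomb_cutoff)))
      }
    }
  }
  hits <- NULL
  if (!is.null(queries) && !is.null(library))
    hits <- screen_library(queries, library,
                           cutoff = config$tanimoto_cutoff,
                           bits = config$fp_bits, type = config$fp_type)
  consensus <- build_consensus(pairing_sets, hits,
                               count_runs = config$count_runs)
  network <- if (nrow(consensus)) build_network(consensus) else NULL
  list(pairing_sets = pairing_sets, hits = hits, consensus = consensus,
       summary = summarize_consensus(consensus), network = network,
       exclusion = exclusion)
}
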