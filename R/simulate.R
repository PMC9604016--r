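# Synthetic-data generators. Every stage of the pipeline is testable
# without docking runs or database downloads: score matrices with a Gaussian
# energy background, systematic ligand-row / target-column offsets and
# planted high-affinity cells; reference/query ligand sets with exact source
# cardinalities and overlaps; and pairing-set fixtures realizing a requested
# confidence-score histogram. All generators are seed-deterministic.
#
# The Gaussian background is deliberate: both post-processing methods are
# mean/SD based, so a Gaussian background gives analytically predictable
# selection rates (about 0.13% of cells beyond the 3-sigma threshold) for
# calibration tests.

#' Configuration for a synthetic docking score matrix
#'
#' Defaults emulate a realistic blind-docking campaign: background binding
#' energies around -7 kcal/mol with SD 1.5, ligand-row and target-column
#' systematic offsets drawn uniformly on +/-1 kcal/mol, and planted
#' high-affinity pairings placed `signal` background-SDs below their cell's
#' expectation.
#'
#' @param n_ligands,n_targets matrix dimensions.
#' @param background_mean,background_sd Gaussian energy background
#'   (kcal/mol); the mean must be negative.
#' @param n_planted number of planted high-affinity pairings (one per
#'   distinct ligand).
#' @param signal planted effect size in background-SD units.
#' @param row_offset_range,col_offset_range half-width of the uniform
#'   systematic offsets (kcal/mol); set 0 for none.
#' @param row_offsets,col_offsets optional explicit offset vectors
#'   (override the ranges).
#' @param missing_fraction fraction of non-planted cells masked as missing,
#'   in \[0, 1).
#' @param seed integer seed; fixed seed means byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ligands = 300L, n_targets = 35L,
                       background_mean = -7, background_sd = 1.5,
                       n_planted = 0L, signal = 4,
                       row_offset_range = 1, col_offset_range = 1,
                       row_offsets = NULL, col_offsets = NULL,
                       missing_fraction = 0, seed = 1L) {
  if (background_mean >= 0)
    stop("background_mean must be negative (binding energies)", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  if (n_planted > n_ligands)
    stop("cannot plant more pairings than ligands", call. = FALSE)
  structure(list(n_ligands = as.integer(n_ligands),
                 n_targets = as.integer(n_targets),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 n_planted = as.integer(n_planted), signal = signal,
                 row_offset_range = row_offset_range,
                 col_offset_range = col_offset_range,
                 row_offsets = row_offsets, col_offsets = col_offsets,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a docking score matrix with planted ground truth
#'
#' Each cell is `background draw + ligand offset + target offset`, minus
#' `signal * background_sd` for planted cells; everything is clamped
#' strictly negative (a configuration that would force a substantial share
#' of non-negative cells is rejected). Planted cells are never masked as
#' missing. The planted pairings are returned alongside the matrix as
#' ground truth.
#'
#' @param cfg a [sim_config()].
#' @param program_label program label for the generated matrix.
#' @return list with elements `matrix` (a [score_matrix()]), `truth`
#'   (data.frame `ligand_id`, `target_id`, `signal`), and the drawn
#'   `row_offsets` / `col_offsets` (named numeric vectors).
#' @export
simulate_score_matrix <- function(cfg, program_label = "simulated") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nl <- cfg$n_ligands; nt <- cfg$n_targets
  lig <- sprintf("L%04d", seq_len(nl))
  tar <- sprintf("T%02d", seq_len(nt))
  r <- cfg$row_offsets
  if (is.null(r)) r <- stats::runif(nl, -cfg$row_offset_range, cfg$row_offset_range)
  cc <- cfg$col_offsets
  if (is.null(cc)) cc <- stats::runif(nt, -cfg$col_offset_range, cfg$col_offset_range)
  s <- matrix(stats::rnorm(nl * nt, cfg$background_mean, cfg$background_sd),
              nl, nt, dimnames = list(lig, tar)) +
    outer(r, rep(0, nt), "+") + outer(rep(0, nl), cc, "+")
  truth <- data.frame(ligand_id = character(), target_id = character(),
                      signal = numeric(), stringsAsFactors = FALSE)
  if (cfg$n_planted > 0L) {
    pl <- sample(nl, cfg$n_planted)               # one plant per ligand
    pt <- sample(nt, cfg$n_planted, replace = TRUE)
    # planted cell = cell expectation + noise - signal*SD, with the noise
    # truncated at +1 SD so every plant sits at least (signal - 1) SDs
    # below its row/column expectation before clamping
    eps <- cfg$background_sd *
      stats::qnorm(stats::runif(cfg$n_planted) * stats::pnorm(1))
    s[cbind(pl, pt)] <- cfg$background_mean + r[pl] + cc[pt] + eps -
      cfg$signal * cfg$background_sd
    truth <- data.frame(ligand_id = lig[pl], target_id = tar[pt],
                        signal = cfg$signal, stringsAsFactors = FALSE)
  }
  nonneg <- s >= 0
  if (mean(nonneg) > 0.05)
    stop("configuration forces non-negative cells (",
         round(100 * mean(nonneg), 1), "% of matrix)", call. = FALSE)
  s[nonneg] <- -1e-3  # clamp strictly negative
  if (cfg$missing_fraction > 0) {
    open <- which(!(seq_along(s) %in%
                      ((match(truth$target_id, tar) - 1L) * nl +
                         match(truth$ligand_id, lig))))
    drop <- sample(open, floor(cfg$missing_fraction * nl * nt))
    s[drop] <- NA_real_
  }
  list(matrix = score_matrix(s, program_label), truth = truth,
       row_offsets = stats::setNames(r, lig),
       col_offsets = stats::setNames(cc, tar))
}

# -- synthetic chemistry ------------------------------------------------

#' Synthetic SMILES pools
#'
#' Enumerates valid SMILES from a small built-in scaffold list with
#' enumerated substituents, so fingerprints behave like real chemistry
#' rather than random strings. The `"reference"` and `"query"` families use
#' disjoint scaffolds, so an un-planted query is structurally far from every
#' reference molecule.
#'
#' @param n number of molecules.
#' @param family `"reference"` or `"query"`.
#' @return character vector of `n` distinct SMILES.
#' @export
synthetic_smiles <- function(n, family = c("reference", "query")) {
  family <- match.arg(family)
  scaffolds <- if (family == "reference")
    c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCCCC1", "c1ccsc1")
  else
    c("C1CCOC1", "C1CCNC1", "c1cnoc1", "C1CCCNC1", "c1cncnc1")
  subs <- c("", "C", "CC", "CCC", "CCCC", "O", "OC", "OCC", "N", "NC",
            "Cl", "F", "Br", "C(=O)O", "C(=O)OC", "C(=O)N", "CN", "S",
            "SC", "C#N", "C(F)(F)F", "OCCO", "NCC", "CCO")
  grid <- expand.grid(pre = subs, core = scaffolds, post = subs,
                      stringsAsFactors = FALSE)
  smi <- unique(paste0(grid$pre, grid$core, grid$post))
  if (n > length(smi))
    stop("synthetic pool exhausted: at most ", length(smi),
         " distinct molecules per family", call. = FALSE)
  smi[seq_len(n)]
}

# Deterministic InChIKey-shaped identifiers for synthetic molecules. These
# are NOT hashes of the structures - they are synthetic stand-ins keyed on
# the pool index, consistent across sources within one simulation.
synthetic_key <- function(idx) {
  v <- as.integer(idx)
  cols <- vector("list", 8L)
  for (p in 8:1) {
    cols[[p]] <- LETTERS[v %% 26L + 1L]
    v <- v %/% 26L
  }
  paste0("SYNKEY", do.call(paste0, cols), "-SIMULATEDF-N")
}

#' Configuration for synthetic reference/query ligand sets
#'
#' @param source_sizes named integer vector of interaction counts per
#'   source (at least two sources).
#' @param overlap number of interactions shared by every pair of sources
#'   (must not exceed the smallest source).
#' @param n_targets number of protein targets the interactions spread over.
#' @param n_queries number of query compounds.
#' @param planted_fraction fraction of queries copied verbatim from
#'   reference molecules (guaranteed Tanimoto-1.0 hits); the rest come from
#'   a disjoint scaffold family.
#' @param seed integer seed.
#' @return list of class `library_sim_config`.
#' @export
library_sim_config <- function(source_sizes = c(bindingdb = 120L, chembl = 150L),
                               overlap = 60L, n_targets = 8L,
                               n_queries = 30L, planted_fraction = 0.3,
                               seed = 1L) {
  if (length(source_sizes) < 2L)
    stop("need at least two sources", call. = FALSE)
  if (overlap > min(source_sizes))
    stop("overlap cannot exceed the smallest source", call. = FALSE)
  if (is.null(names(source_sizes)))
    names(source_sizes) <- paste0("source", seq_along(source_sizes))
  sizes <- stats::setNames(as.integer(source_sizes), names(source_sizes))
  structure(list(source_sizes = sizes,
                 overlap = as.integer(overlap),
                 n_targets = as.integer(n_targets),
                 n_queries = as.integer(n_queries),
                 planted_fraction = planted_fraction,
                 seed = as.integer(seed)),
            class = "library_sim_config")
}

#' Simulate reference-interaction sources and a query compound table
#'
#' Builds a universe of distinct (target, ligand) interactions of size
#' `sum(sizes) - (k-1) * overlap` and distributes it so that every source
#' realizes exactly its configured size and every pair of sources shares
#' exactly the configured overlap (the first `overlap` interactions are
#' common to all sources). Ligand molecules are drawn from the reference
#' scaffold pool; their structure keys are synthetic, deterministic and
#' consistent across sources. A `planted_fraction` of the queries copy
#' reference SMILES verbatim and are recorded in the planted-hit list; the
#' remaining queries come from a disjoint scaffold family.
#'
#' @param cfg a [library_sim_config()].
#' @return list with `sources` (named list of interaction data.frames in
#'   the [load_interactions()] layout), `queries` (data.frame
#'   `compound_id`, `smiles`), and `planted` (data.frame `compound_id`,
#'   `target_id`, `ligand_key`: every target association of each copied
#'   molecule).
#' @export
simulate_reference_sets <- function(cfg) {
  stopifnot(inherits(cfg, "library_sim_config"))
  set.seed(cfg$seed)
  sizes <- cfg$source_sizes
  k <- length(sizes)
  n_universe <- sum(sizes) - (k - 1L) * cfg$overlap
  targets <- sprintf("T%02d", seq_len(cfg$n_targets))
  # assign interactions to targets round-robin; ligand index unique within
  # target, molecules recycled across targets from the reference pool
  tgt <- targets[(seq_len(n_universe) - 1L) %% cfg$n_targets + 1L]
  within <- stats::ave(seq_len(n_universe), tgt, FUN = seq_along)
  pool_n <- max(within)
  pool <- synthetic_smiles(pool_n, "reference")
  uni <- data.frame(target_id = tgt,
                    ligand_key = synthetic_key(within),
                    smiles = pool[within],
                    stringsAsFactors = FALSE)
  # first `overlap` rows shared by all sources; the rest partitioned
  idx <- cfg$overlap
  sources <- vector("list", k)
  for (i in seq_len(k)) {
    own <- sizes[i] - cfg$overlap
    rows <- c(seq_len(cfg$overlap),
              if (own > 0) idx + seq_len(own))
    idx <- idx + max(own, 0L)
    src <- uni[rows, , drop = FALSE]
    src$source_label <- names(sizes)[i]
    rownames(src) <- NULL
    sources[[i]] <- src
  }
  names(sources) <- names(sizes)
  # queries
  n_plant <- round(cfg$planted_fraction * cfg$n_queries)
  qid <- sprintf("Q%03d", seq_len(cfg$n_queries))
  plant_rows <- if (n_plant > 0) sample(n_universe, n_plant) else integer()
  q_smiles <- c(uni$smiles[plant_rows],
                synthetic_smiles(cfg$n_queries - n_plant, "query"))
  queries <- data.frame(compound_id = qid, smiles = q_smiles,
                        stringsAsFactors = FALSE)
  planted <- if (n_plant > 0) {
    copied_keys <- uni$ligand_key[plant_rows]
    assoc <- uni[uni$ligand_key %in% copied_keys,
                 c("target_id", "ligand_key")]
    m <- merge(data.frame(compound_id = qid[seq_len(n_plant)],
                          ligand_key = copied_keys,
                          stringsAsFactors = FALSE),
               assoc, by = "ligand_key")
    m[order(m$compound_id, m$target_id),
      c("compound_id", "target_id", "ligand_key")]
  } else
    data.frame(compound_id = character(), target_id = character(),
               ligand_key = character(), stringsAsFactors = FALSE)
  rownames(planted) <- NULL
  list(sources = sources, queries = queries, planted = planted)
}

#' Simulate pairing sets realizing a confidence-score histogram
#'
#' Constructs synthetic target-ligand pairings and assigns each one to
#' exactly the required number of distinct approaches, so that consensus
#' fusion of the returned inputs reproduces the requested histogram. The
#' approach universe is the standard five channels: two post-processing
#' methods on two programs, plus the similarity screen. Approach
#' combinations rotate deterministically over the pairings of each score.
#'
#' @param counts named vector: `counts[["3"]]` pairings with confidence 3,
#'   etc. Scores above 5 are rejected.
#' @param programs labels of the two docking programs.
#' @param seed integer seed (placement is deterministic given the seed).
#' @return list with `pairing_sets` (list of [pairing_set()], one per
#'   target-based approach that received pairings) and `hits` (a
#'   `similarity_hits` data.frame for the ligand-based channel).
#' @export
simulate_pairing_sets <- function(counts, programs = c("progA", "progB"),
                                  seed = 1L) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    return(list(pairing_sets = list(), hits = NULL))
  scores <- as.integer(names(counts))
  if (any(is.na(scores) | scores < 1L))
    stop("`counts` must be named by confidence scores", call. = FALSE)
  universe <- c(paste("method1", programs, sep = ":"),
                paste("method2", programs, sep = ":"), "similarity")
  if (any(scores > length(universe)))
    stop("requested score exceeds the approach universe (",
         length(universe), ")", call. = FALSE)
  set.seed(as.integer(seed))
  total <- sum(counts)
  lig <- sprintf("SL%05d", seq_len(total))
  tar <- sprintf("ST%02d", (seq_len(total) - 1L) %% 20L + 1L)
  assign <- vector("list", length(universe))
  names(assign) <- universe
  i <- 0L
  for (s in seq_along(scores)) {
    combos <- utils::combn(length(universe), scores[s])
    for (j in seq_len(counts[s])) {
      i <- i + 1L
      cmb <- combos[, (j - 1L) %% ncol(combos) + 1L]
      for (a in universe[cmb])
        assign[[a]] <- c(assign[[a]], i)
    }
  }
  pairing_sets <- list()
  hits <- NULL
  for (a in universe) {
    rows <- assign[[a]]
    if (length(rows) == 0L) next
    if (a == "similarity") {
      hits <- data.frame(compound_id = lig[rows], target_id = tar[rows],
                         tanimoto = 1.0,
                         best_reference_key = NA_character_,
                         stringsAsFactors = FALSE)
      class(hits) <- c("similarity_hits", "data.frame")
    } else {
      mp <- strsplit(a, ":", fixed = TRUE)[[1]]
      pairing_sets <- c(pairing_sets,
                        list(pairing_set(tar[rows], lig[rows],
                                         method = mp[1], program = mp[2])))
    }
  }
  list(pairing_sets = pairing_sets, hits = hits)
}
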