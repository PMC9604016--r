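# Chemistry fixtures: a handful of small, well-known molecules.
FIX <- list(
  benzoic1 = "OC(=O)c1ccccc1",
  benzoic2 = "c1ccccc1C(=O)O",   # same molecule, different spelling
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  phenol = "c1ccccc1O",
  ethanol = "CCO",
  methane = "C",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C")

test_that("interaction tables load, canonicalize and drop bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_id\tsmiles",
               paste("T1", FIX$benzoic1, sep = "\t"),
               paste("T1", FIX$aspirin, sep = "\t"),
               paste("T2", FIX$phenol, sep = "\t")), f)
  ints <- load_interactions(f, "src")
  expect_equal(nrow(ints), 3L)
  expect_true(all(nzchar(ints$ligand_key)))
  expect_equal(attr(ints, "n_dropped"), 0L)

  # row with invalid SMILES is dropped and counted
  writeLines(c("target_id\tsmiles",
               paste("T1", FIX$ethanol, sep = "\t"),
               "T1\tnot_a_smiles((("), f)
  expect_message(ints2 <- load_interactions(f, "src"), "dropped 1")
  expect_equal(nrow(ints2), 1L)
  expect_equal(attr(ints2, "n_dropped"), 1L)

  # two spellings of one molecule share a structure key
  writeLines(c("target_id\tsmiles",
               paste("T1", FIX$benzoic1, sep = "\t"),
               paste("T2", FIX$benzoic2, sep = "\t")), f)
  ints3 <- load_interactions(f, "src")
  expect_equal(ints3$ligand_key[1], ints3$ligand_key[2])

  writeLines(c("target_id\tsmiles", "T1\tzzz((("), f)
  expect_error(suppressMessages(load_interactions(f, "src")), "no parsable")
})

test_that("library merging is a union on (target, key) with bookkeeping", {
  a <- data.frame(target_id = c("T1", "T1", "T2"),
                  ligand_key = c("K1", "K2", "K1"),
                  smiles = "C", source_label = "A", stringsAsFactors = FALSE)
  b <- data.frame(target_id = c("T1", "T2", "T2"),
                  ligand_key = c("K2", "K1", "K9"),
                  smiles = "C", source_label = "B", stringsAsFactors = FALSE)
  lib <- merge_libraries(list(a, b))
  st <- attr(lib, "merge_stats")
  expect_equal(unname(st$source_sizes), c(3L, 3L))
  expect_equal(st$overlaps["A", "B"], 2L)
  expect_equal(st$union_size, 4L)
  expect_equal(nrow(lib), 4L)

  # idempotence: merging a set with itself is the set
  self <- merge_libraries(list(a, a))
  expect_equal(nrow(self), 3L)
})

test_that("merging obeys inclusion-exclusion on random source pairs", {
  set.seed(77)
  universe <- expand.grid(target_id = paste0("T", 1:6),
                          ligand_key = paste0("K", 1:40),
                          stringsAsFactors = FALSE)
  for (rep in 1:25) {
    ia <- sample(nrow(universe), sample(20:120, 1))
    ib <- sample(nrow(universe), sample(20:120, 1))
    a <- cbind(universe[ia, ], smiles = "C", source_label = "A")
    b <- cbind(universe[ib, ], smiles = "C", source_label = "B")
    lib <- merge_libraries(list(a, b))
    st <- attr(lib, "merge_stats")
    expect_equal(st$union_size,
                 sum(st$source_sizes) - st$overlaps["A", "B"])
    expect_equal(st$union_size, length(union(ia, ib)))
  }
})

test_that("fingerprints are deterministic and canonical-invariant", {
  fp <- fingerprint(c(FIX$benzoic1, FIX$benzoic1, FIX$benzoic2,
                      FIX$methane, FIX$caffeine))
  expect_equal(ncol(fp), 2048L)
  expect_identical(fp[1, ], fp[2, ])          # determinism
  expect_identical(unname(fp[1, ]), unname(fp[3, ]))  # spelling-invariant
  expect_true(sum(fp[4, ]) != sum(fp[5, ]))   # different chemistry differs
  expect_error(fingerprint("junk((("), "junk")
})

test_that("the Tanimoto coefficient satisfies its identities", {
  fp <- fingerprint(c(FIX$aspirin, FIX$phenol))
  expect_equal(tanimoto(fp[1, ], fp[1, ]), 1)
  a <- rep(FALSE, 16); a[c(1, 2, 3)] <- TRUE
  b <- rep(FALSE, 16); b[c(2, 3, 4)] <- TRUE
  expect_equal(tanimoto(a, b), 0.5)           # |{2,3}| / |{1,2,3,4}|
  d <- rep(FALSE, 16); d[9] <- TRUE
  expect_equal(tanimoto(a, d), 0)             # disjoint
  expect_equal(tanimoto(logical(16), logical(16)), 0)  # both empty
  expect_error(tanimoto(a, b[1:8]), "length")
  # symmetry and bounds on real fingerprints
  expect_equal(tanimoto(fp[1, ], fp[2, ]), tanimoto(fp[2, ], fp[1, ]))
  expect_gte(tanimoto(fp[1, ], fp[2, ]), 0)
  expect_lte(tanimoto(fp[1, ], fp[2, ]), 1)
})

test_that("the similarity screen finds planted ligands and is monotone", {
  lib <- merge_libraries(data.frame(
    target_id = c("T1", "T1", "T2", "T2", "T3"),
    ligand_key = paste0("K", 1:5),
    smiles = c(FIX$aspirin, FIX$caffeine, FIX$benzoic1, FIX$phenol,
               FIX$ethanol),
    source_label = "src", stringsAsFactors = FALSE))
  queries <- data.frame(compound_id = c("Q1", "Q2"),
                        smiles = c(FIX$benzoic2, FIX$methane),
                        stringsAsFactors = FALSE)
  hits <- screen_library(queries, lib, cutoff = 0.75)
  # Q1 is benzoic acid, an exact structural match of T2's reference
  expect_true(any(hits$compound_id == "Q1" & hits$target_id == "T2" &
                    hits$tanimoto == 1))
  # with cutoff 1.0 only exact matches survive
  exact <- screen_library(queries, lib, cutoff = 1)
  expect_true(all(exact$tanimoto == 1))
  # monotonicity: raising the cutoff only removes hits
  h50 <- screen_library(queries, lib, cutoff = 0.5)
  h80 <- screen_library(queries, lib, cutoff = 0.8)
  k <- function(h) paste(h$compound_id, h$target_id)
  expect_true(all(k(h80) %in% k(h50)))
  expect_true(all(k(hits) %in% k(h50)))
})

test_that("screen results match an exhaustive all-pairs oracle", {
  ls <- simulate_reference_sets(library_sim_config(
    source_sizes = c(a = 30L, b = 40L), overlap = 10L, n_targets = 4L,
    n_queries = 12L, planted_fraction = 0.25, seed = 5))
  lib <- merge_libraries(ls$sources)
  cutoff <- 0.75
  hits <- screen_library(ls$queries, lib, cutoff = cutoff)
  qfp <- fingerprint(setNames(ls$queries$smiles, ls$queries$compound_id))
  uref <- lib[!duplicated(lib$ligand_key), ]
  rfp <- fingerprint(setNames(uref$smiles, uref$ligand_key))
  # brute force: loop every (query, target, reference) triple
  expected <- list()
  for (q in ls$queries$compound_id) {
    for (t in unique(lib$target_id)) {
      refs <- lib[lib$target_id == t, ]
      best <- -1; bestkey <- NA
      for (r in seq_len(nrow(refs))) {
        tc <- tanimoto(qfp[q, ], rfp[refs$ligand_key[r], ])
        if (tc > best) { best <- tc; bestkey <- refs$ligand_key[r] }
      }
      if (best >= cutoff)
        expected[[paste(q, t)]] <- c(best = best, key = bestkey)
    }
  }
  got <- setNames(hits$tanimoto, paste(hits$compound_id, hits$target_id))
  expect_setequal(names(got), names(expected))
  for (nm in names(expected))
    expect_equal(unname(got[nm]), as.numeric(expected[[nm]]["best"]),
                 tolerance = 1e-12)
})

test_that("empty or unusable inputs are handled gracefully", {
  lib0 <- merge_libraries(data.frame(target_id = character(),
                                     ligand_key = character(),
                                     smiles = character(),
                                     source_label = character(),
                                     stringsAsFactors = FALSE))
  q <- data.frame(compound_id = "Q1", smiles = FIX$ethanol,
                  stringsAsFactors = FALSE)
  expect_warning(h <- screen_library(q, lib0), "empty")
  expect_equal(nrow(h), 0L)
  expect_error(screen_library(q, lib0, cutoff = 0), "cutoff")
})

test_that("mean pairwise similarity follows the all-pairs definition", {
  expect_equal(mean_pairwise_similarity(c(FIX$benzoic1, FIX$benzoic2)), 1)
  expect_equal(mean_pairwise_similarity(rep(FIX$aspirin, 4)), 1)
  smi <- c(FIX$aspirin, FIX$phenol, FIX$caffeine)
  fp <- fingerprint(smi)
  hand <- mean(c(tanimoto(fp[1, ], fp[2, ]), tanimoto(fp[1, ], fp[3, ]),
                 tanimoto(fp[2, ], fp[3, ])))
  expect_equal(mean_pairwise_similarity(smi), hand, tolerance = 1e-12)
  expect_message(na <- mean_pairwise_similarity(FIX$ethanol), "undefined")
  expect_true(is.na(na))
})
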