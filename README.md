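# invscreen

Dual inverse virtual screening for target identification in R.

Given compounds known to be bioactive but with unknown molecular targets —
the typical outcome of phenotypic or high-throughput screens — inverse
screening ranks candidate protein targets per compound instead of
candidate compounds per protein. `invscreen` implements the statistical
layer of such a campaign around two complementary evidence families:

* **Target-based:** post-processing of blind-docking ligand×target
  binding-energy matrices (kcal/mol; one matrix per docking program) with
  two independent methods —

  * **Method I**, quotient normalization
    `V = V0 / ((ML + MT) / 2)` (ML, MT the ligand-row and target-column
    mean energies) followed by selection of all cells with
    `V ≥ M + 3σ`, which cancels ligand- and target-wide systematic score
    shifts and keeps only the globally outstanding pairings;
  * **Method II**, a two-directional Z-transformation:
    `ZT` standardizes each cell across targets, `ZL` across ligands,
    `Zcomb = 0.7·ZT + 0.3·ZL`, and the target with the lowest `Zcomb` is
    selected for each ligand.

* **Ligand-based:** a similarity screen of the query compounds against
  reference-interaction libraries merged from database exports
  (deduplicated on target id + full InChIKey), using circular
  Morgan-type fingerprints (OpenBabel ECFP4, folded to 2048 bits) and the
  Tanimoto coefficient with an inclusive 0.75 cutoff.

Evidence from all five channels (2 methods × 2 docking programs + the
similarity screen, each docking channel run with and without promiscuous
targets) is fused into unique target–compound pairings with confidence
scores 1–5 (= number of distinct supporting approaches), and projected
onto a protein–ligand interaction network whose edge weights count shared
ligands. Seed-deterministic simulators generate score matrices with
planted binders and reference/query ligand sets with exact cardinalities,
so the whole pipeline is testable without docking runs or database
dumps.

## Worked example

A fully synthetic end-to-end run: two docking programs' matrices with ten
planted high-affinity pairings each, plus a two-source reference library
with a third of the queries planted as exact copies of reference ligands.

```r
library(invscreen)

simA <- simulate_score_matrix(sim_config(n_ligands = 120, n_targets = 15,
                                         n_planted = 10, seed = 11), "smina")
simB <- simulate_score_matrix(sim_config(n_ligands = 120, n_targets = 15,
                                         n_planted = 10, seed = 12), "qvina-w")
refs <- simulate_reference_sets(library_sim_config(
  source_sizes = c(bindingdb = 80L, chembl = 90L), overlap = 30L,
  n_targets = 8L, n_queries = 25L, planted_fraction = 0.3, seed = 13))
lib <- merge_libraries(refs$sources)
lib
#> reference_library: 140 unique interactions, 8 targets
#>   sources: bindingdb=80, chembl=90

res <- run_inverse_screen(list(simA$matrix, simB$matrix),
                          queries = refs$queries, library = lib)
res$consensus
#> consensus_table: 298 unique target-ligand pairings
#>   confidence: 3:2  2:20  1:276
head(as.data.frame(res$consensus), 2)
#>   target_id ligand_id confidence                                  approaches
#> 1       T04     L0011          3 method1:smina;method2:qvina-w;method2:smina
#> 2       T06     L0038          3 method1:qvina-w;method2:qvina-w;...
```

The union of the two sources is 80 + 90 − 30 = 140 interactions. Of the
298 consensus pairings, two were found by three independent approaches —
in a real campaign these would be the first candidates for experimental
follow-up. `res$summary` holds the score histogram, ligands-per-target and
targets-per-ligand distributions, and the structure-based/ligand-based
overlap; `res$network` is an igraph object (71 edges here) exportable with
`export_network()` as an edge table, SIF, or GraphML.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "invscreen", package = "invscreen")` with
subcommands `simulate`, `postprocess`, `similarity`, `network` and
`run-all`.

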