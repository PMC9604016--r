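---
title: "Dual inverse screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual inverse screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscreen)
```

## The problem

Inverse (reverse) virtual screening turns the usual drug-discovery question
around: instead of ranking compounds against one protein, it ranks candidate
protein targets for compounds already known to be active — for example,
compounds that rescue CFTR function in cell assays but whose molecular
target is unknown. `invscreen` implements the statistical core of such a
campaign: it does **not** run docking, but post-processes the
ligand-by-target binding-energy matrices that blind docking produces, runs a
complementary ligand-based similarity screen, and fuses all evidence into
consensus confidence scores and protein–ligand interaction networks.

Two properties of raw inverse-docking matrices motivate the statistics:

* **Target-wide bias.** Scoring functions systematically favour some
  receptors (larger pockets, more hydrophobic surface), so a raw "best
  energy per ligand" rule mostly ranks receptors, not interactions.
* **Ligand-wide bias.** Larger, greasier ligands score better against
  every target.

Both post-processing methods are designed to cancel these row- and
column-wise shifts.

## Method I — quotient normalization with a 3σ rule

Each energy $V_0$ (kcal/mol, negative, more negative = stronger) is
replaced by

$$V = \frac{V_0}{(M_L + M_T)/2},$$

where $M_L$ is the mean energy of the ligand's row and $M_T$ of the
target's column (defined cells only). Because numerator and denominator are
both negative, $V$ is positive and larger $V$ means relatively stronger
binding; multiplying the matrix by any positive constant leaves $V$
unchanged. Pairings are selected where $V \ge M + 3\sigma$, with $M$ and
$\sigma$ the mean and population standard deviation of all defined $V$.

Numerical decisions:

* The comparison is **inclusive** — the threshold names an admissible
  boundary. On a constant matrix ($\sigma = 0$) every defined cell equals
  $M$ and all pass; the degenerate case is logged rather than hidden.
* All standard deviations in the package are **population** SDs (divide by
  $n$), so the matrix-wide $\sigma$ and the axis SDs of method II share one
  convention. The published description does not say which convention was
  used; at the matrix sizes involved the difference is far below every
  decision boundary.
* Non-negative cells are masked during validation before normalization: a
  mixed-sign matrix would make the quotient non-monotone. Missing cells are
  excluded from every mean/SD and can never be selected; they are never
  imputed.

## Method II — two-directional Z-transformation

Every cell is standardized along both axes:
$Z_T$ within its ligand row (across targets) and $Z_L$ within its target
column (across ligands), each as $(x_i - \bar{x})/SD$ with population SDs.
The combined score is

$$Z_{comb} = 0.7\,Z_T + 0.3\,Z_L,$$

and for each ligand the target with the **lowest** $Z_{comb}$ is selected
(energies are negative, so lowest = strongest relative binding). There is no
score cutoff by default: every ligand with at least one defined $Z_{comb}$
yields exactly one pairing. An optional cutoff is available but off.

The published wording does not pin down which Z-score standardizes which
axis. We take $Z_T$ = across targets (row-wise, per ligand): the dominant
0.7 weight then corrects the per-ligand score shift before receptors are
compared, which is the stated intent of the two-directional transform. The
opposite assignment is available as `orientation = "swapped"` in
`ztransform_2d()`.

Degenerate inputs: a zero-SD axis contributes $Z = 0$ for all its cells
(logged); rows or columns with fewer than two defined cells are dropped with
a warning; exact ties in the per-ligand argmin are broken lexicographically
by target id, deterministically.

### What the normalizations can and cannot cancel

Method I's quotient cancels row and column offsets almost completely: in
simulations with ±1 kcal/mol column offsets and no signal, the per-target
counts of selected pairings stay chi-square-uniform. Method II is different
**by construction**: $Z_T$ standardizes within rows, so a column-constant
shift survives into $0.7\,Z_T$, and only the $0.3\,Z_L$ term removes it.
Method II therefore *reduces* column bias strongly relative to raw-minimum
selection (its chi-square statistic drops by far more than half in the
bundled test) but does not eliminate it. The test suite asserts exactly
these two properties rather than pretending both methods are equally
bias-free.

## Promiscuous-target exclusion

Because both methods use per-ligand averages over all targets, one target
that attracts anomalously many strong scores (a promiscuous kinase, say)
distorts every other target's statistics. The remedy is to drop that
target's column and re-run the whole docking analysis; the similarity
screen is unaffected, since it never touches docking statistics.
`detect_promiscuous()` defaults to a manually curated list (mirroring how
such exclusions are decided in practice); an automatic policy flags targets
whose ligand count exceeds median + 5·MAD (unscaled MAD) of the per-target
counts.

Consensus over runs: an approach that identifies a pairing in either run
(with or without exclusions) supports it **once**. Counting approach×run
combinations instead is available (`count_runs = TRUE`) but would inflate
the intended 1–5 score range.

## Ligand-based similarity screen

Reference interactions are merged from multiple database exports, keyed on
(target id, full InChIKey). The full key — not the 14-character
connectivity block — is deliberate: exports routinely distinguish
stereoisomers, and collapsing them would merge genuinely different actives.
Fingerprints are OpenBabel ECFP4 — circular atom-environment (Morgan-type)
fingerprints of radius 2 — folded from their native 4096 bits to 2048
(configurable). Similarity is the Tanimoto coefficient, and a query becomes
a potential ligand of a target when its best similarity against that
target's references reaches 0.75 (inclusive; less restrictive than the
common 0.85). Each (query, target) pair records only the single
best-matching reference; multiple above-cutoff references do not multiply
evidence. Note that different fingerprint implementations assign bits
differently, so absolute Tanimoto values are comparable only within one
fingerprint type; every property the package guarantees (determinism,
canonical-SMILES invariance, the Tanimoto identities, cutoff monotonicity)
is representation-independent.

## Confidence scores and networks

The approach universe has five members: {method I, method II} × {program A,
program B} plus the similarity screen. A pairing's confidence is the number
of distinct approaches supporting it, 1–5; 5 requires unanimity. The
protein–ligand interaction network projects the (confidence-filtered)
bipartite associations onto targets: edge weight = number of shared
ligands, node attributes = ligand count and degree, isolated targets kept
as degree-0 nodes so per-target counts remain visible.

## What the simulators emulate

`simulate_score_matrix()` draws a Gaussian energy background (default mean
−7, SD 1.5 kcal/mol — a realistic scale for blind-docking scores), adds
uniform ±1 kcal/mol row and column offsets as the systematic biases the
methods must cancel, and plants high-affinity cells `signal` SDs (default
4) below their cell expectation. Plant noise is truncated at +1 SD, so
every planted cell is guaranteed at least (signal − 1) SDs below its
expectation; all cells are clamped strictly negative, and planted cells are
never masked as missing. The Gaussian background makes selection rates
analytically predictable: method I on pure noise selects ≈ 0.135% of cells
(the one-sided 3σ tail), which the calibration test verifies within
Monte-Carlo error.

`simulate_reference_sets()` realizes exact source sizes and pairwise
overlaps (the first `overlap` interactions are common to all sources), so
merge arithmetic is exercised at any printed cardinality without chemistry
costs: ligand structure keys are deterministic synthetic stand-ins
(`SYNKEY…` — recognisably not real InChIKeys), while the molecules
themselves come from a scaffold-plus-substituent enumeration of valid
SMILES. Query sets mix exact copies of reference molecules (guaranteed
Tanimoto-1.0 hits, recorded as ground truth) with molecules from a disjoint
scaffold family.

What the synthetic data does **not** model: program-specific score
distributions, score correlation between docking programs, non-Gaussian
energy tails, chemically clustered reference libraries, or
activity-threshold curation of database exports. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated — not that
any particular biological pairing from a real campaign would be recovered.

## Operating characteristics of the 3σ rule

A fixed 3σ threshold has an intrinsic precision/recall trade-off that no
parameter choice can evade. On a 300×35 matrix with 30 plants at 4 SD,
roughly 10 500 background cells leave ≈ 8–14 false positives beyond the
(plant-inflated) threshold, against at most 30 true positives: measured
over seeds 1–10, method I recovers 92% of plants at a false-discovery rate
of ≈ 20%, and the rate moves only marginally across realistic background
parameters. Method II, which must select exactly one target per ligand,
names the planted target for 98% of planted ligands under the same
conditions. The bundled acceptance test asserts recall ≥ 80%, FDR ≤ 20%
and per-ligand hit rate ≥ 90%; the FDR sits at the boundary and can fall on
either side of it by fractions of a point depending on seeds.

## Problem sizes

The test-suite and acceptance-script simulations use 100×100 noise matrices
(10 seeds), 300×35 recovery matrices (10 seeds), reference libraries up to
the published cardinalities (≈ 66 000 interaction rows, synthetic keys),
and chemistry on the order of a few hundred molecules — sizes chosen so the
full statistical story is told in seconds on one core.
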