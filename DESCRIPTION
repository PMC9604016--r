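Package: invscreen
Title: Inverse Virtual Screening by Docking-Score Post-Processing and
    Ligand Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Target identification for bioactive compounds by combining two
    complementary inverse (reverse) screening routes. Post-processes blind
    docking ligand-by-target score matrices with two independent statistical
    methods (quotient normalization with a three-sigma selection threshold,
    and a two-directional Z-transformation with per-ligand best-target
    selection), screens query compounds against merged reference interaction
    libraries with circular fingerprints and the Tanimoto coefficient, fuses
    all evidence channels into consensus confidence scores, and projects the
    resulting target-compound associations onto weighted protein-ligand
    interaction networks. Ships seed-deterministic simulators for score
    matrices with planted binders and for reference/query ligand sets, so the
    whole pipeline is testable without docking runs or database exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
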