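Package: locohd
Title: Local Composition Hellinger Distance for Protein Structure Comparison
Version: 0.1.0
Authors@R:
    person("LoCoHD", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the local composition Hellinger distance (LoCoHD), a
    chemically aware metric comparing the local environments of anchor atoms
    between protein structures. Structures are mapped to primitive-atom clouds
    under full-atom or coarse-grained typing schemes (optionally with
    per-residue centroid sites); the environment of each anchor is summarised
    by distance-dependent composition vectors, and pairs of environments are
    scored by a weight-averaged Hellinger distance with an exact
    piecewise-constant closed form. Ships the surrounding analysis workflows:
    ensemble distance matrices with Kabsch RMSD and complete-linkage
    clustering, reference-vs-model per-residue scoring with external score
    joins, trajectory time series with Sarle's bimodality screening, and
    random residue-pair score-distribution statistics with beta-distribution
    fits. A synthetic-fixture generator and a command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
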