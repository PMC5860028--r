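Package: fragdock
Title: Motif-Guided FFT Docking of Peptide Fragments to Protein Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global rigid-body docking of short linear peptide motifs to a
    free receptor structure. The protocol builds a backbone fragment library
    by wildcard motif search over a structure database (with a sequence
    identity exclusion filter and iterative motif generalization or
    restriction to reach a target library size), clusters the fragments by
    superposed backbone RMSD with a greedy algorithm, rigidly docks each
    cluster representative to the receptor by FFT cross-correlation of
    weighted energy grids (repulsive core, attractive shell and Coulombic
    terms), then clusters the pooled poses in the receptor frame, ranks
    clusters by size, removes poses overlapping declared domain-domain
    interfaces, and evaluates predictions against a native complex with the
    CAPRI acceptable-accuracy peptide criterion (4.0 Angstrom backbone RMSD).
    Includes a deterministic synthetic fixture generator (toy receptors with
    a planted binding pocket, planted native complexes, fragment databases
    with controlled motif-match counts) so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
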