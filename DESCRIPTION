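Package: pdbalign
Title: Two-Phase Protein Structure Alignment and Structural Neighbour
    Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise protein structure alignment and one-against-all
    structural neighbour searching from backbone C-alpha traces.  A fast
    secondary-structure-string filter based on longest-common-subsequence
    length screens candidate pairs; survivors receive a fragment-based
    residue-level alignment that maximises the TM-score through Kabsch
    superposition, dynamic programming, gapless threading and multi-part
    template splitting.  Includes PDB chain parsing, a DSSP-output reader
    with a geometric fallback secondary-structure assigner, and
    generators of synthetic C-alpha traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
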