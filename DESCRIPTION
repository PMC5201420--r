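Package: paircoev
Title: Inter-Protein Sequence Coevolution from Organism-Paired Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects residue-residue contacts between interacting protein
    families from sequence coevolution. Two per-family multiple sequence
    alignments are paired by organism and concatenated; coupled column pairs
    are scored with three methodologically distinct scorers (mean-field
    direct coupling analysis, sparse L1-penalised inverse covariance, and
    mutual information), corrected with the average product correction, and
    thresholded at a chosen number of standard deviations above the mean.
    Predicted contacts can be filtered by membrane topology, classified
    against a reference structure, and exported as docking restraints.
    Includes phylogenetic subsetting of a protein family with organism
    co-occurrence filtering and per-column sequence-logo information
    content, plus a fully deterministic synthetic-data generator with
    planted inter-chain couplings for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
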