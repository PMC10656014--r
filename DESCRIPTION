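Package: probeam
Title: Beam Search Decoding of Single-Molecule Fluorosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies peptides from single-molecule fluorosequencing
    light-intensity reads with a beam search decoder over a compact
    (N, K, R) state space: remaining labelable residues per fluorophore
    color, remaining attached fluorophores, and the removed dye-sequence
    prefix.  Models Edman degradation failure, dye miss, dye loss and
    peptide detachment with Gaussian intensity emissions.  Includes in
    silico tryptic digestion and dye-sequence construction, a matched
    generative read simulator, an exact maximum-a-posteriori decoder by
    trajectory enumeration for verification on small instances, and
    evaluation utilities (split-based accuracy, precision-recall,
    posterior calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
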