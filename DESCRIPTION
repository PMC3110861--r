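Package: accalign
Title: Solvent-Accessibility-Dependent Gap Penalties for Template-Target
    Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise global alignment of a target amino acid sequence
    against a template of known three-dimensional structure, where the
    gap-opening penalty decays exponentially with the template residue's
    relative solvent accessibility. Includes a Shrake-Rupley accessible
    surface area calculator with per-residue-type normalisation, the
    binned gap odds-ratio statistics (with bootstrap errors and linear
    and log-linear regressions) that motivate the penalty, alignment
    evaluation scores against reference structural alignments (Q-score,
    insertion segment and point precision, over/under-assignment
    coordinates), brute-force grid fitting of the penalty parameters, a
    minimal progressive multiple aligner, and a synthetic indel
    simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    withr
Config/testthat/edition: 3
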