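Package: foldscan
Title: Sliding-Window Thermodynamic Scanning of RNA Secondary Structure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fragments DNA or RNA sequence into overlapping windows, folds
    each window on both strands under a nearest-neighbor thermodynamic
    model, and archives five per-window metrics: minimum free energy (MFE),
    a shuffle-null thermodynamic z-score, an empirical p-value, ensemble
    diversity, and the Boltzmann frequency of the MFE structure. Runs of
    consecutive low z-score windows are concatenated into candidate
    structured domains, and results are written as GFF3, consolidated CSV,
    and strand-split per-metric bedGraph tracks. Includes a compiled
    folding engine (minimum free energy dynamic programming and a
    McCaskill-style partition function with pair probabilities), an
    exhaustive-enumeration oracle for short sequences, an adapter for
    external Turner-parameter engines such as RNAfold, and a synthetic
    chromosome generator with embedded hairpins for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    optparse,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
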