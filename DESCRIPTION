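Package: srnaprofiler
Title: Ovarian Small-RNA Profiling of Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative small-RNA analysis of
    transposable elements (TEs) in Drosophila ovaries: adapter trimming,
    length and quality filtering, ncRNA subtraction, strand-aware mapping of
    reads to TE consensus sequences at fixed mismatch strata, siRNA/piRNA
    size-class quantification with CPM normalization and a low-expression
    floor, ping-pong (secondary piRNA processing) signatures with 1U/10A
    nucleotide biases, consensus-divergence profiling, per-position coverage
    tracks, and cross-strain asymmetry calls with Venn-style intersections
    and Spearman profile correlations. Includes a seeded synthetic-data
    generator with a per-read ground-truth table, and deterministic
    calculators for 2^-ddCt qPCR and percent-input ChIP-qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stringi,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
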