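Package: genotax
Title: Genome-Based Taxonomy and Physiology of Bacterial Isolates
Version: 0.1.0
Authors@R:
    person("Genotax", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for genome-based re-classification of
    bacterial isolates and characterisation of their physiology. Implements
    fragment-based average nucleotide identity (ANI) with directional aligned
    fractions, reciprocal-best-hit average amino-acid identity (AAI) and
    dendrograms, pan/core gene-family accumulation curves, concatenated-marker
    neighbor-joining phylogenies with bootstrap, window-based GC content and
    GC-skew profiles, dinucleotide composition-anomaly scans, hemE-anchored
    oriC prediction with DnaA-box and duplex-unwinding-element detection,
    RpsL streptomycin-resistance residue calling, and growth-kinetics fitting
    for nitrate respiration (doubling times, nitrate-to-nitrite stoichiometry,
    nitrite toxicity). Ships simulators for genome sets with planted truth and
    for anaerobic growth series so every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
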