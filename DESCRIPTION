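Package: surfaceomics
Title: Surfaceome Determination for Gram-Positive Bacteria from Proteomic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to determine the surface proteome (surfaceome) of a
    Gram-positive bacterium from standard proteomics and sequence-analysis
    outputs. Parses transmembrane-helix scan, PSORTb-style and LocateP-style
    localization predictions and hmmscan per-domain tables; derives a
    consensus subcellular compartment per protein with an explicit evidence
    hierarchy; classifies the surface-binding mechanism from cell-wall
    binding domains, lipoprotein and LPxTG flags and membrane anchors;
    normalizes label-free spectral counts, calls differential expression
    between growth conditions with a fold/absolute-count/error rule, and
    scores dimethyl-label log-ratios with an intensity-binned robust outlier
    statistic (significance B). Includes cross-experiment membership tallies,
    function-by-localization cross-tabulations, a qPCR delta-delta-Ct helper,
    and a ground-truthed synthetic data generator emulating a two-extraction,
    two-condition surface-proteomics study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
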