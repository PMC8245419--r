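Package: rhodevo
Title: Structure-Based Clustering and Photocycle Kinetics of Light-Driven Proton Pumps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two analyses of microbial (type 1) rhodopsin proton pumps:
    structure-based phylogenetic clustering of 7-transmembrane-helix bundles with a
    per-residue Calpha positional-conservation metric (pairwise Calpha superposition
    with iterative outlier rejection, RMSD-matrix hierarchical clustering,
    conservation profiles paintable into B-factors), and global multiexponential
    analysis of flash-photolysis transient-absorption surfaces with reconstruction
    of absolute intermediate spectra under a sequential irreversible photocycle
    (variable-projection lifetime fitting, component-count selection by weighted
    residual SD, Bateman cascade concentrations, cycling-fraction determination by
    spectral non-negativity). Also includes geometric annotations (hydrogen bonds,
    Shrake-Rupley solvent-accessible surface area, dimer interface area),
    first-derivative melting-point detection for thermal-unfolding curves, and a
    synthetic-data module that generates structure families and photocycle datasets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    bio3d,
    Biostrings,
    ape,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
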