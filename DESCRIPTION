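Package: idpscape
Title: Differential Conformational-Landscape Analysis for Disordered Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares labeled conformational ensembles of intrinsically
    disordered proteins in a single shared two-dimensional "effective
    conformational space". Pairwise dissimilarities between conformations are
    computed from a Gaussian-weighted agreement of all internal C-alpha
    distances (the Q_w order parameter), embedded in the plane by the
    force-scheme technique, and compared with grid-based statistics: per-bin
    relative fractions, density overlaps between ensembles, and projection
    entropies. Local conformational signatures (distance-RMSD medoids with
    contact maps) characterise selected regions, and a cylindrical-sector
    module stratifies a bound-partner trajectory by binding mode. Includes a
    synthetic polymer-ensemble generator for end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
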