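Package: poremapr
Title: Hydrophobicity Mapping and State Classification of Ion-Channel Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the permeation pathway of tetrameric ion
    channels from static structures and molecular-dynamics frames. Computes
    molecular hydrophobicity potential (MHP) fields from atomic logP
    contributions, ray-traces van der Waals surfaces onto cylindrical
    projection maps of the pore and of single pore-lining helices,
    reimplements HOLE-style pore-radius profiling with gate-minimum
    extraction, scores per-residue 3D-1D environment profiles and their
    cross-state correlations, measures water-exposed (Connolly) surface
    area and water/ion density profiles over trajectory windows, detects
    pi-bulges in pore-lining helices, and classifies pore states
    (alpha-closed, pi-closed, pi-open, intermediate). Ships a synthetic
    C4-symmetric pore generator so the full stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
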