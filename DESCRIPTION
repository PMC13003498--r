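Package: nanosponge
Title: Automated Guest Identification in Crystalline Sponges from Residual Density Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which organic guest molecule occupies the pores of a
    crystalline-sponge host from a list of residual electrostatic-potential
    maxima (Q-peaks). Q-peaks are filtered, expanded under space-group
    symmetry, clustered into putative molecular skeletons using periodic
    minimum-image connectivity, and matched against candidate molecules
    generated from SMILES strings by maximum-clique correspondence search
    and Kabsch rigid-body superposition. Candidates are ranked by RMSD and
    coverage, the best match is placed as an initial carbon-skeleton model
    with element-reassignment suggestions, and host-guest contacts
    (coordination bonds, hydrogen bonds, offset pi-stacking, van der Waals)
    are classified together with the symmetry-clash cap on site occupancy.
    Includes SHELX res/ins and CIF readers/writers and a seeded synthetic
    Q-peak simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    ChemmineOB,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
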