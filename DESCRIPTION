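Package: grindqsar
Title: Grid-Independent Descriptor 3D-QSAR with Pharmacophore Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free 3D-QSAR modelling of receptor antagonists from
    molecular interaction fields. Computes probe interaction energies
    (Lennard-Jones, electrostatic, hydrogen bond) on a regular grid around
    3D structures, discretizes each field into an energy/spread-filtered
    node set, encodes node pairs into auto- and cross-correlogram
    (grid-independent, GRIND) descriptors, and links them to pIC50 by
    partial least squares with fractional-factorial-design variable
    selection. Includes activity-table curation (molar pIC50, lipophilic
    efficiency, diversity-based train/test splitting), distance-geometry
    pharmacophore models with conformer matching and dataset screening, a
    validation suite (MCC, Q2/SDEP, Roy rm2, standardization-approach
    applicability domain), and a synthetic pseudo-compound generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    Rcpp,
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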