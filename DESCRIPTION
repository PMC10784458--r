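Package: gpcrstates
Title: Conformational State Annotation of Class A GPCR Structures and Trajectories
Version: 0.1.0
Authors@R: person("gpcrstates", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates class A G protein-coupled receptor (GPCR) structures
    and molecular dynamics trajectories as active- or inactive-like. A
    receptor conformation is encoded as an ordered vector of pairwise
    distances between side-chain geometric centers of activation-pathway
    residue pairs (GPCRdb generic numbering); tree-ensemble classifiers
    trained on labelled conformational ensembles score each frame with an
    active-state probability, expose interpretable decision paths and
    feature importances, and whole trajectories are classified by the
    fraction of active frames. Includes leakage-free trajectory-stratified
    dataset construction, binding-site RMSD analysis with rank-sum group
    comparison, minimal PDB/DCD readers and writers, and a synthetic
    conformational-ensemble generator with known ground truth for offline
    testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
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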