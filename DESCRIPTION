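Package: elscreen
Title: Electrostatics-Driven Rescoring for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rescoring of pre-placed ligand poses against a protein target
    using the electrostatic field of the ligand-free protein. Solves the
    linearized Poisson-Boltzmann equation on a cubic grid, evaluates
    protein-sourced electrostatic potentials at ligand-atom sites, and
    combines electrostatic, hydrophobic, and van der Waals replacement
    energies (relative to the co-crystallized cognate ligand) with
    spherical-harmonics shape similarity and chemometric descriptor
    similarity into a weighted Z-score ranking. Includes Gasteiger (PEOE)
    partial charges, Shrake-Rupley solvent-accessible surface areas,
    atom-pair fingerprints, screen evaluation (ROC/AUC, relative enrichment
    factors), competition-binding assay helpers (percent-of-control, Hill
    dissociation-constant fits), and a seedable synthetic pocket/ligand
    fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    igraph,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
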