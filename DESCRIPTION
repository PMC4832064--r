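Package: pepmetad
Title: Metadynamics Free-Energy Reconstruction and Reweighted Ensemble
    Analysis for Phospho-Regulated Disordered Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how phosphorylation reshapes the conformational
    ensemble of an intrinsically disordered peptide. Provides annotated
    peptide sequences with phospho-residue flags and Cdk1 S/T-P consensus
    motif scanning; analytic energy landscapes and a coarse-grained charged
    bead-chain surrogate sampled by BAOAB Langevin dynamics; collective
    variables (radius of gyration, C-alpha contact number with a rational
    switching function); standard and well-tempered metadynamics with
    hill-based free-energy-surface reconstruction and convergence
    diagnostics; time-dependent-bias frame reweighting; weighted
    GROMOS-style conformational clustering with Boltzmann cluster free
    energies; residue-pair contact-probability maps and salt-bridge /
    hydrogen-bond surrogate detection; and PLUMED-style COLVAR/HILLS,
    FASTA, XYZ and frame-PDB text I/O with a reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
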