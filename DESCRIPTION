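Package: trajlens
Title: Conformational Trajectory Analysis and MM/GBSA Binding Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular dynamics conformational ensembles at desk
    scale: mass-weighted Kabsch superposition with RMSD time series and
    per-residue RMSF profiles, principal component analysis of positional
    fluctuations and functional mode analysis (the collective mode maximally
    Pearson-correlated with a scalar functional quantity, with its
    ensemble-weighted variant and cross-validation), pairwise-RMSD hierarchical
    clustering with Davies-Bouldin, pseudo-F and SSR/SST cluster-count
    selection and medoid centroids, and single-trajectory MM/GBSA binding free
    energies (Coulomb, Lennard-Jones, Hawkins-Cramer-Truhlar generalized Born,
    Shrake-Rupley surface area) with per-residue decomposition. Includes
    seed-deterministic synthetic-trajectory generators with planted collective
    modes, multi-state ensembles and toy receptor-ligand complexes so every
    stage has recoverable ground truth, plus a declarative pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
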