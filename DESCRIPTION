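Package: basinselect
Title: Energy-Landscape Basin Decomposition for Protein Decoy Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects near-native models (decoys) from template-free protein
    structure prediction ensembles by embedding the ensemble in an epsilon
    nearest-neighbor graph under pairwise least RMSD, decomposing the graph
    plus per-decoy energies into basins of the energy landscape via
    steepest-ratio discrete gradient descent, and ranking basins by size,
    by supervised purity prediction with Pareto-dominance and graph features,
    and by per-decoy weights derived from predicted RMSD or density scores.
    Includes energy-blind clustering baselines (k-means with knee selection,
    Louvain communities), union-find sublevel-set persistence, purity and
    RMSD-loss evaluation metrics, and a seeded synthetic-ensemble generator
    with planted funnels and false minima.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    xgboost,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
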