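Package: gaplearn
Title: Active Learning of Sparse Gaussian-Process Interatomic Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training reactive machine-learned force fields with a
    minimal number of reference ("ground truth") evaluations. Implements sparse
    Gaussian-process potentials on many-body atomic-environment descriptors
    (two-body, three-body and a SOAP-style power spectrum), an intra- plus
    inter-molecular energy decomposition with expanded-box evaluation, an
    episode-scheduled active-learning loop with energy-error ('diff') and
    predictive-variance ('gp_var') acceptance rules, Langevin molecular
    dynamics, nudged-elastic-band path relaxation, and the prospective
    cumulative-error validation metric tau_acc. Ships cheap analytic surrogate
    ground-truth potentials (a flexible water model and a two-state empirical
    valence bond surface) so the full workflow runs end-to-end without any
    external electronic-structure code. Reads and writes multi-frame extended
    XYZ files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
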