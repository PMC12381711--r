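Package: deltaqc
Title: Delta-Learning Energy Corrections from Local Density-Matrix
    Eigen-Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifts cheap baseline electronic-structure energies toward
    coupled-cluster quality by learning the energy difference between a
    high-level and a low-level method. Rotation-invariant features are the
    eigenvalues of atom-local density matrices obtained by projecting the
    occupied baseline orbitals onto atom-centred auxiliary Gaussian shells;
    an atom-wise neural network with a ridge linear pre-fit maps them to a
    correction energy. Includes a self-contained desk-scale electronic
    structure engine (Gaussian integrals, restricted Hartree-Fock, CCSD(T)
    reference energies), reaction-record management with grouped dataset
    splits, a synthetic fixture generator, and reaction-energy /
    barrier-height / minimum-energy-path evaluation with MAE and RMSE
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
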