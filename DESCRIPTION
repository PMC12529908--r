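Package: lessemb
Title: Huzinaga-Equation DFT-in-DFT Embedding with Local Basis-Set Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density-fitted restricted Kohn-Sham and Hartree-Fock engine with
    Huzinaga-equation and level-shift-projector quantum embedding, allowing a
    hybrid functional to be applied to an active subsystem inside a GGA
    description of the full molecule.  The high-level subsystem calculation is
    accelerated by net-Mulliken-population truncation of the atomic-orbital
    basis and by three reduction schemes for the density-fitting auxiliary
    basis: natural auxiliary functions, generalized Mulliken charges on fitting
    functions, and local density-fitting shell domains.  Includes a built-in
    Gaussian integral backend (McMurchie-Davidson), PBE/PBE0 exchange-
    correlation on a Becke molecular grid, in-core and integral-direct Fock
    assembly, external point-charge embedding, deterministic closed-shell test
    fixture generators, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
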