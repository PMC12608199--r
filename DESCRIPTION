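Package: hpfold
Title: Partition-Function Zeros and Folding Kinetics of HP Lattice Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact thermodynamics and folding kinetics of hydrophobic-polar
    (HP) protein chains on the simple cubic lattice.  Provides exhaustive
    enumeration of self-avoiding conformations with contact-energy
    bookkeeping, exact densities of states and partition polynomials in
    x = exp(1/kT), high-precision partition-function (Fisher) zeros, the
    per-zero decomposition of the heat capacity used to locate the collapse
    and folding transitions, a screen of the full 2^N sequence space for
    unique-ground-state (protein-like) sequences, and a rejection-free
    Gillespie kinetic Monte Carlo simulator of first-passage folding times
    under corner-flip and 90-degree end-flip dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
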