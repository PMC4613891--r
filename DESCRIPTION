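Package: eemkit
Title: Conformationally Sensitive Atomic Charges by Electronegativity
    Equalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calculates empirical partial atomic charges for molecular
    systems of any size with the Electronegativity Equalization Method
    (EEM). Provides the full dense EEM solve together with two
    fragment-based approximations (a per-atom cutoff scheme and a
    covering-subset scheme) that keep memory bounded by the largest
    fragment, reads and writes common structure formats (PDB, PQR, MOL,
    MOL2, SDF) with charges, manages EEM parameter sets in an XML
    template, aggregates charges to residues and groups, compares charge
    sets, and evaluates linear QSPR models that map charge descriptors to
    pKa with Henderson-Hasselbalch ionization fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
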