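Package: cgphase
Title: Coarse-Grained Simulation and Analysis of Peptide Condensates with
    Switchable Cation-Pi Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying liquid-liquid phase separation of model
    intrinsically disordered peptides with a three-class coarse-grained bead
    model (positive, negative, aromatic). Implements Debye-Hueckel screened
    electrostatics, 12-6 dispersion terms for pi-pi and (switchable) cation-pi
    contacts, excluded-volume repulsion and harmonic bonded terms; an
    underdamped Langevin dynamics engine for many-chain systems in periodic
    boxes; condensate identification by single-linkage chain clustering;
    dense/dilute phase densities and binodal fitting with a fixed critical
    exponent (beta = 0.325); per-polymer energy gain, mean-squared-displacement
    diffusivity with condensate-residency filtering, and gyration-tensor shape
    anisotropy. Also provides Das-Pappu kappa and sequence-charge-decoration
    patterning metrics, a Monte-Carlo sequence designer targeting kappa, and a
    binned charge-versus-aromatic-content analysis of intrinsically disordered
    regions with linear trend fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    igraph,
    minpack.lm,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
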