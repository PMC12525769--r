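Package: pbsq
Title: Phycobilisome Quenching, Energy Transfer and Global Lifetime Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for time-resolved fluorescence of
    phycobilisomes (PBS) and their quenching by orange carotenoid proteins
    (OCP). Provides a hierarchical composition model of PBS architecture with
    bilin-stoichiometry censuses; extraction of bilin chromophores from PDB or
    mmCIF coordinate files with mass-center distance networks and
    excitation-energy-transfer adjacency graphs; a compartmental
    energy-transfer cascade simulator producing time-resolved emission spectra
    (TRES) with Gaussian instrument-response convolution and Poisson photon
    noise; global reconvolution analysis of TRES by variable projection,
    yielding shared lifetimes and decay-associated spectra (DAS); and
    quenching metrics including component yields, quenching efficiency,
    Bliss-independence additivity (Jin's Q), quench time-course fits and
    Arrhenius activation-energy estimation for the OCP photocycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
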