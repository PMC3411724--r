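Package: mmtweezers
Title: Force Fields, Tether Dynamics and DNA Elasticity for Multiplexed
    Magnetic Tweezers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for multiplexed magnetic tweezers (MMT)
    experiments on DNA-bead tethers: a 3D magnetostatic charge-sheet model of
    the field and force produced by an antiparallel permanent-magnet pair,
    Langevin magnetization of superparamagnetic beads, worm-like-chain (WLC)
    elasticity with the Bouchiat seven-parameter correction, an overdamped
    Langevin simulator of tethered-bead dynamics with Faxen wall-corrected
    drag, bicircular (Limacon) analysis of bead rotation patterns, and a
    high-throughput elasticity-characterization pipeline (surface and
    attachment-offset corrections, equipartition force calibration,
    energy-versus-extension fitting, ensemble statistics). A synthetic
    experiment generator produces complete multiplexed data sets so the whole
    pipeline can be exercised without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
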