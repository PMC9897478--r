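Package: ionsans
Title: Small-Angle Neutron Scattering and Structural-Dynamics Analysis of
    Pentameric Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of pentameric ligand-gated ion channel
    structure against small-angle neutron scattering (SANS) data. Predicts
    solution scattering curves from atomic models via a histogram-accelerated
    Debye sum under a deuterium-contrast model with hydrogen-deuterium
    exchange and transmembrane shielding; performs Guinier and pair-distance
    distribution analysis (including a regularized indirect Fourier
    transform), molecular-weight estimation from forward scattering, and
    chi-square fitting of model curves to experimental data. Adds
    channel-specific geometry: HOLE-style pore-radius profiles anchored at
    the 9' gate, domain center-of-mass tracking in cylindrical coordinates,
    per-frame ensemble ranking against SANS curves, and Cartesian PCA
    conformational landscapes. A synthetic C5 toy-channel generator with
    mobile peripheral lobes provides ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
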