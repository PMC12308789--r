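Package: protomeR
Title: Gas-Phase Protonation-State Ranking for Ion-Mobility Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the equilibrium gas-phase charge state ([M+H]+ or
    [M-H]-) of a small molecule for ion-mobility mass spectrometry.
    Titratable nitrogen and oxygen sites are enumerated, each candidate
    protomer is featurized with ten steric and electronic descriptors
    (including the center-of-electronegativity descriptor and a
    Shrake-Rupley molecular surface area), ranked by a gradient-boosted-tree
    relative-energy regressor, pruned with an acceptance-capacity heuristic,
    refined by a short geometry optimization under a pluggable potential
    backend, and reported with final rankings, relative energies and
    Boltzmann mole fractions.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
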