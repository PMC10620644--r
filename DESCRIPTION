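Package: oximescreen
Title: In Silico Screening Toolkit for Oxime Reactivators of
    Organophosphate-Inhibited Acetylcholinesterase
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computational screening of pyridinium-aldoxime
    (2-PAM class) reactivator candidates against organophosphate-inhibited
    acetylcholinesterase: enumeration of electron-donating-group substituted
    analogs, CNS drug-likeness and blood-brain-barrier threshold filtering,
    near-attack (apical) pose geometry classification from PDB coordinates,
    two-layer subtractive (ONIOM2) energy combination with delta-energy
    counting, ranking and quartile selection, pair-interaction-energy (PIEDA)
    fingerprints and interaction-residue consensus, a distance-based
    selection molecular dynamics (DS-MD) adaptive-sampling engine driven by a
    toy overdamped Langevin propagator, and Markov-state-model free-energy
    landscapes on the approach-distance/attack-angle plane with minima and
    minimax barrier analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
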