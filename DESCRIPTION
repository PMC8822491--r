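Package: autoxkin
Title: Kinetics of Antioxidant-Inhibited Lipid Peroxidation in Micelles and
    Liposomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of oxygen-uptake kinetics for
    azo-initiated peroxidation of methyl linoleate dispersed in surfactant
    micelles or phospholipid liposomes and inhibited by phenolic antioxidants.
    Provides a deterministic reaction-network model of the peroxyl-radical
    chain (initiation, propagation, termination, chain-breaking inhibition,
    phenoxyl coupling to trapping-competent dimers, and co-antioxidant
    regeneration), closed-form steady-state oracles, a seeded generator of
    Clark-electrode-like oxygen-uptake traces, and an inference pipeline that
    recovers induction periods, initiation rates, stoichiometric factors,
    inhibited peroxidation rates, inhibition rate constants, kinetic chain
    lengths, and antioxidant synergy metrics from such traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
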