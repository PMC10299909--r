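Package: gpcrsel
Title: Quantifying Efficacy-Driven Agonist Selectivity at G-Protein-Coupled Receptors
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pharmacological curve models and molecular-dynamics state metrics
    for dissecting whether an agonist's receptor-subtype selectivity is driven
    by binding affinity or by signaling efficacy. Implements one-site
    saturation and one/two-site competition radioligand binding fits with
    Cheng-Prusoff conversion, the Black-Leff operational model of agonism with
    expression-corrected efficacy (tau_C), an exact ternary-complex
    (ligand/receptor/G-protein) mass-action equilibrium solver with
    cooperativity estimation and state free energies, threshold classifiers
    for trajectory-derived geometric features (side-chain chi1 rotamers and
    inter-helix C-alpha distances) with per-simulation state frequencies,
    percentile-bootstrap confidence intervals and the Mann-Whitney U test, and
    seeded synthetic-data generators so that every stage is testable against
    known ground truth. A command-line interface ties the stages into
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
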