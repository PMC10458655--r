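Package: hostfit
Title: Force-Field Evaluation and Force-Matching Refit for Macrocyclic Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A gas-phase molecular-mechanics toolkit for evaluating and
    refitting classical force fields of ring-shaped (macrocyclic) host
    molecules. Provides an AMBER-style intramolecular energy and force
    engine with analytic gradients, restrained electrostatic-potential
    (RESP) charge fitting with the ESP relative root-mean-squared error
    metric, Metropolis Monte Carlo configurational sampling, a regularized
    force-matching refit of bonded parameters against a reference
    Hamiltonian with adaptive data accumulation, and evaluation and
    dynamics analyses (energy RMSE/MAE, atom-resolved force errors,
    per-unit error decomposition, structural superposition, radius-of-
    gyration state classification). A synthetic-data module generates toy
    macrocycles and ground-truth parameter sets so the complete workflow
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
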