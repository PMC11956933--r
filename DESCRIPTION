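Package: clawcbgt
Title: Boolean State-Transition Analysis of Cortico-Basal
    Ganglia-Thalamic Decision Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two-choice decision making in a stochastic
    population-rate model of the cortico-basal ganglia-thalamic (CBGT)
    circuit with direct, indirect and pallidostriatal pathways, and
    analyses the resulting firing-rate trajectories with the CLAW
    framework (Circuit Logic Assessed via Walks): histogram-based
    binarization of binned rates, base-2 encoding of Boolean activity
    patterns into integer states, estimation and pruning of the
    state-transition graph, partition of states into functional zones,
    drift-diffusion model simulation and maximum-likelihood fitting, and
    canonical correlation analysis linking network activity to
    decision-policy parameters through three control ensembles (choice,
    responsiveness, pliancy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
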