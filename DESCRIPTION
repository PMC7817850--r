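Package: actinf
Title: Discrete-State Active Inference with Representational and Deontic Action Pathways
Version: 0.1.0
Authors@R: person("A.", "Meridian", email = "a.meridian@example.org", role = c("aut", "cre"))
Description: An engine for discrete-state (POMDP-style) active inference agents
    with two coexisting routes to action. The representational route performs
    approximate Bayesian state inference by variational free-energy
    minimization and plans by softmax selection over expected free energy,
    with its epistemic/instrumental decomposition. The deontic route maps
    observed cues directly to policies through a learned policy-conditioned
    outcome likelihood, bypassing state inference and planning altogether.
    Includes generative-model validation and JSON serialization, a fixture
    generator, an agent-environment simulator that keeps the generative
    process distinct from the generative model, habit-acquisition
    experiments, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
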