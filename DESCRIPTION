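Package: ppcons
Title: Parallel-Pathway Models of Systems Memory Consolidation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how Hebbian
    spike timing-dependent plasticity (STDP) in parallel synaptic
    pathways can transfer memories from an indirect, delayed pathway
    into a direct shortcut pathway. Provides the kernel-level drift
    coefficient theory (stability and consolidation coefficients from
    learning windows and input correlation kernels), a conductance-based
    leaky integrate-and-fire neuron with additive STDP for weight-copy
    and spatial-replay experiments, a rate-based multi-stage hippocampal
    network with object-place memory imprinting, Bayesian place decoding
    and lesion experiments, a hierarchical neocortical cascade producing
    memory waves and power-law forgetting, and the linear overlap-ODE
    theory of hierarchical consolidation. All inputs are generated
    in-package by seeded synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
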