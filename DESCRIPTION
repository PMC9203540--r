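Package: coxtcm
Title: Transit-Compartment Tumor Growth Models with Erlang and Coxian Delay Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling drug-perturbed tumor growth with transit
    compartment models (TCMs) whose delayed cell-death kernels are phase-type
    distributions. Implements the classical Erlang (Simeoni-type) chain and its
    Coxian generalization, in which damaged cells may die suddenly at any
    transit stage with probability 1 - p. Includes a two-compartment
    pharmacokinetic driver with multi-bolus and constant-infusion dosing, a
    convolution-form master-equation oracle for the distributed-delay
    formulation, closed-form equilibrium and stability analysis under constant
    infusion, nonlinear least-squares parameter estimation with the
    range-normalized RMSE goodness-of-fit metric, and seeded synthetic-data
    generators emulating a mouse xenograft regimen and a tumor-spheroid
    constant-concentration assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
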