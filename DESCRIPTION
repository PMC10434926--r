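Package: ensir
Title: Ensemble Bayesian Inference of Unobserved Infections on Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates unobserved infections on contact networks from sparse,
    time-stamped individual test results. Implements a discrete-time stochastic
    SIR simulator with node-heterogeneous transmission rates, state-dependent
    testing and contact-tracing observation models, per-node SIR master
    equations, and an ensemble Bayesian inference algorithm that combines
    backward temporal propagation of observations with a cross-ensemble
    covariability (Kalman-regression) update. Ships competing risk-ranking
    baselines (degree, contact with observed infections, modified dynamic
    message passing) and ROC/AUC and top-k evaluation utilities, together with
    a reproducible experiment driver and a runtime scaling benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
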