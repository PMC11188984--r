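Package: prongscape
Title: Multiscale Species Distribution and Habitat Consensus Modelling
Version: 0.1.0
Authors@R: person("Prongscape", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a multiscale workflow for
    mapping current and future habitat of a wide-ranging arid-grassland
    ungulate: Maxent-style penalized presence/background climate models with a
    regularization sweep and AIC selection, projection onto an ensemble of
    perturbed future climate stacks with a mobility-oriented parity (MOP)
    extrapolation screen, three independent habitat models (a four-learner
    ensemble resource selection function, a step-selection function fitted by
    stratified conditional logistic regression, and an expert habitat
    suitability index), occurrence-percentile thresholding, climate clipping,
    and a 0-3 consensus map with conflict-class masking and area accounting.
    Includes a synthetic-landscape and movement-track generator with known
    ground truth so every stage is verifiable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    FNN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
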