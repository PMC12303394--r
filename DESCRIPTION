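Package: tauspread
Title: Connectome-Based Reaction-Diffusion Modelling of Tau Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the progression of pathological tau protein
    across the human structural connectome. Implements a family of network
    reaction-diffusion models (local and global Fisher-KPP, pure network
    diffusion, regional logistic growth, and the coupled heterodimer system)
    on a volume-weighted graph Laplacian, with regionally varying baseline
    SUVR and carrying capacities estimated from cross-sectional tau PET via
    two-component Gaussian mixtures. Includes hierarchical Bayesian
    calibration of subject-level transport and production rates with an
    adaptive Markov chain Monte Carlo sampler, posterior-predictive
    forecasting of individual regional trajectories, model comparison by BIC
    and expected log predictive density, a spatial-shuffle control analysis,
    and seed-deterministic synthetic cohort generators for end-to-end
    validation without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
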