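Package: intgrad
Title: Intrinsic Neural Timescales and Hierarchical Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation of intrinsic neural timescales (INT) from resting-state
    fMRI autocorrelation, data-driven selection of sensory cortical hierarchies
    from structural MRI, symptom-specific hierarchical-gradient inference with
    permutation and accelerated bias-corrected bootstrap statistics, and a
    hierarchical excitatory-inhibitory rate-network simulator with a
    Balloon-Windkessel hemodynamic forward model and excitation-inhibition
    perturbation fitting. Includes seeded synthetic-data generators emulating
    the statistical structure of every input so the full pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    Rcpp,
    RNifti,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
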