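Package: motionscrub
Title: Motion Censoring and Functional Connectivity Evaluation for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools to quantify and mitigate head-motion artifacts in
    resting-state fMRI, with an emphasis on the high-motion fetal setting.
    Computes framewise displacement (FD), scaled DVARS and temporal
    signal-to-noise ratio; performs simultaneous volume censoring, nuisance
    regression (6/12/24/36 motion regressor sets via Volterra expansion,
    tissue principal components) and spectral band-pass filtering in one
    leakage-free least-squares step; builds functional-connectivity (FC)
    profiles with autocorrelation-corrected Fisher z-scores; screens residual
    motion effects on BOLD time series, individual connections and whole-brain
    FC profiles; evaluates censoring thresholds via connectome-based
    prediction of motion versus neurobiological targets (linear SVR/SVC with
    fold-internal feature selection, repeated cross-validation and permutation
    nulls); and runs seed-based group contrasts with cluster-extent
    thresholding. A synthetic-data generator with known ground truth
    (intermittent motion spikes, spike-locked distance-dependent BOLD
    artifacts, covariate effects on designated connections) supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
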