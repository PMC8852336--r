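Package: specstab
Title: Intra-Session Stability of Spectral Estimates from Resting-State Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much resting-state recording time is needed
    for robust region-level spectral estimates. Implements permutation-based
    split-half intraclass-correlation (ICC(A,1)) stability curves over
    progressively longer data durations, Welch band-power pipelines,
    aperiodic/periodic (1/f + Gaussian peak) spectral parameterization,
    minimal-duration threshold tables, participant subsampling analyses, and
    leave-one-out individual stability-contribution scores with frequentist
    and Jeffreys-Zellner-Siow Bayesian covariate tests. Includes synthetic
    generators with exact variance-component and spectral ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
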