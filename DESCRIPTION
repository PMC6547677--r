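Package: dyadsync
Title: Dyadic Autonomic Synchrony from Interbeat Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying physiological synchrony between interacting
    partners from electrocardiogram-derived interbeat intervals. Provides
    artifact flagging and correction for interbeat-interval series,
    segmentation into overlapping epochs, per-epoch autonomic indices
    (Cardiac Sympathetic Index from the Lorenz plot and log respiratory
    sinus arrhythmia from a 0.12-0.40 Hz band-limited heart-period signal),
    residualized-change reactivity scores, three-level dyadic mixed models
    with autoregressive residuals for concurrent synchrony, a pseudo-dyad
    permutation null, multivariate multilevel models relating synchrony and
    reactivity to affiliation outcomes with Tukey-adjusted simple effects,
    and a synthetic dyad generator with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    emmeans,
    signal,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
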