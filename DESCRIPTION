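Package: gaitfnirs
Title: Ambulatory fNIRS Analysis of Freezing of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing and hierarchical Bayesian analysis of ambulatory
    functional near-infrared spectroscopy (fNIRS) recordings acquired during
    overground gait tasks in people with freezing of gait. Covers conversion of
    dual-wavelength intensities to haemoglobin concentration changes via the
    modified Beer-Lambert law, signal-quality channel pruning, spline and
    wavelet correction of direct movement artifacts, short-separation-channel
    and head-kinematics confound regression, band filtering and per-run
    z-scoring, video-annotation merging with inter-rater agreement metrics,
    kinematic gait-event detection, event-locked baseline-corrected epoching
    over cortical regions of interest, and Bayesian hierarchical linear mixed
    models (group, condition and freezing-severity models) fitted by MCMC.
    Includes a synthetic session generator with known ground truth emulating
    the gait protocol, so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'bayes.R'
    'confound.R'
    'epoch.R'
    'events.R'
    'gaitevents.R'
    'hrf.R'
    'io.R'
    'mbll.R'
    'montage.R'
    'normalize.R'
    'pipeline.R'
    'preprocess.R'
    'synth.R'
    'synth_session.R'
    'utils.R'
    'wavelet.R'
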