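Package: deltamotor
Title: Delta-Band EEG Analysis of Movement Initiation and Directional
    Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for delta-band EEG studies of
    center-out reaching. Provides a synthetic-data generator with a
    single-sphere forward model (movement-related cortical potentials,
    direction-tuned parieto-occipital sources, eye artifacts), the full
    preprocessing chain (zero-phase Butterworth filtering, spherical-spline
    channel interpolation, regression-based eye-artifact correction, common
    average reference, variance-based transient artifact removal,
    resampling), cursor movement-onset detection and behavioral statistics,
    two-pass statistical epoch rejection, a per-timepoint linear encoding
    model (GLM) with analytic shrinkage covariance, sLORETA source imaging
    with global-field-power normalization, shrinkage-LDA decoding with
    leave-one-trial-out cross-validation and label-shuffling significance
    levels, and group-level sign-flip and paired permutation tests with
    Benjamini-Hochberg FDR control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
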