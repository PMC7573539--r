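---
title: "Delta-band EEG analysis of movement initiation and directional processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-band EEG analysis of movement initiation and directional processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltamotor)
```

## The scientific question and the analysis it requires

During a visually guided center-out reach, two distinct processes leave
traces in low-frequency (delta band, < 3 Hz) EEG: *movement initiation*,
expressed as the movement-related cortical potential (MRCP) — a slow
negativity over sensorimotor cortex phase-locked to the movement onset —
and *directional processing*, expressed as parieto-occipital activity
phase-locked to the cue that reveals the target direction. Separating the
two requires analyzing the same trials under two alignments (trial/cue
onset vs. detected movement onset) and asking, for each alignment, where
direction and condition information live on the cortex and how well they
can be decoded from single trials.

`deltamotor` implements that full analysis as a reusable pipeline, and —
because no public recordings accompany the design — ships a synthetic-data
generator that emulates the study conditions end to end, with ground truth
for every latent quantity (movement onsets, source waveforms, artifact
mixing). All analysis stages are exercised against that generator.

## The synthetic experiment

One subject is one simulated session: 360 trials (180 execution, 180
observation; 4 directions, balanced), 64 EEG + 6 EOG channels at 200 Hz, a
normalized cursor-distance trace at 60 Hz, the condition cue at 2.0 s and
the direction cue at 2.5 s of every trial. Ground-truth movement onsets
are drawn from a truncated Normal(3.23, 0.18) s and movement durations
from Normal(0.49, 0.13) s. Cursor traces are minimum-jerk reaches with a
jittery resting baseline. A calibration recording (rest in the first half,
scripted blinks and large saccades in the second) accompanies each
session, mirroring the dedicated artifact blocks such experiments record.

Neural activity enters the channels through an analytic single-sphere
dipole leadfield (Legendre series, 100 terms; conductivity 0.33 S/m,
radius 9 cm). The source space (voxel layout, ROI sectors) and the
direction-tuning map are tied to a cohort-level `leadfield_seed`, not the
subject seed: every subject of a cohort shares one anatomy, exactly as
template-head-model source imaging assumes, so group-level averaging of
coefficient maps across subjects is well defined. Trial sequences, onsets,
noise and artifacts remain subject-specific. A boundary-element head model would add anatomical realism
but no analytical content: every downstream stage only requires a known
linear source-to-channel mixing. Three source components are simulated:

* **MRCP** in sensorimotor voxels (contralateral weighted 2:1),
  Gaussian-rise/exponential-decay negativity peaking 100 ms before the
  movement onset; the execution-condition projection is calibrated to
  −2.3 µV at the central contralateral channel, and the observation
  condition is scaled by 0.3 (≈ −0.7 µV).
* **Visual responses** in occipital voxels after both cues (slow
  Gaussian-windowed cycle, +3 µV occipital peak).
* **Direction tuning** in parieto-occipital voxels: each voxel has a
  random preferred direction and responds with the cosine of the angle
  between trial and preferred direction, in a bump peaking 350 ms after
  the direction cue. Because random preferences can cancel at any single
  electrode, this component is calibrated by its channel-space maximum.

All three templates are explicitly slow: ≥ 95 % of their spectral energy
lies below 3 Hz (asserted by a periodogram test), so the delta-band chain
passes them through.

Noise is spatially correlated pink noise mixed through 80 random deep
dipole topographies — deliberately more topographies than channels. A
low-rank noise model looks superficially similar but leaves noise-free
spatial directions that make any signal perfectly decodable; full-rank
noise is what real EEG provides. Eye artifacts are driven by the gaze
traces (a catch-up saccade 190 ms after the direction cue, occasional
blinks) mixed into the EEG with a frontally weighted topography.

**Amplitude calibration.** The published record states channel-space ERP
peaks but not source amplitudes or noise levels, so two free parameters
were fixed once, by matching the cohort's decoding effect sizes to the
reported ones: `noise_sd = 2` µV and `dir_peak = 0.3` µV give
condition-classification peaks near 0.8 and cue-aligned four-class
direction peaks near 0.6 with movement-aligned peaks near 0.4 — the
regime the study reports (78–80 %, 44 %, 35.5 %) — without ceiling
effects. These defaults were frozen before the acceptance suite was
written and are not revisited per run.

**Calibration-block length.** The eye-artifact correction is a regression
fitted on calibration data only. Its coefficient error scales inversely
with the artifact energy in the calibration recording, and any error is
multiplied by the large, direction-locked task gaze regressors —
too short a calibration block injects a spurious, cue-locked "direction
signal" into the corrected EEG. With the default 300 s block (scripted
saccades at 1.5× task amplitude every 2.5 s, blinks every 2 s) the
injected component decodes at chance; at 40 s it decodes far above
chance. This mirrors why such studies record several minutes of dedicated
artifact calibration.

## Preprocessing chain

Stages run in a fixed order, asserted at run time: 0.4 Hz high-pass +
50 Hz notch (4th-order Butterworth, zero-phase) → spherical-spline
interpolation of bad channels → eye-artifact correction → common average
reference → HEAR (transient high-variance artifact removal) → 3 Hz
low-pass → resampling to 10 Hz. Notable numerical choices:

* **Zero-phase filtering** uses steady-state initial conditions plus odd
  reflection padding, so constants are annihilated by the high-pass to
  machine precision and edges are transient-free; the two-pass magnitude
  response is the squared single-pass Butterworth response, which the
  tests verify against the closed form.
* **Eye correction** regresses every EEG channel on three EOG-derivative
  regressors (right−left outer canthus; superior−inferior per eye) plus
  the first principal component of the EOG during calibration blink
  segments, fitted on calibration data only and subtracted from the task
  data; EOG channels pass through untouched for the behavioral analysis.
  This is a deliberate simplification of sparse subspace-subtraction
  algorithms: it matches their behavior exactly when contamination is
  linear in the artifact sources, which is the regime the generator
  produces and the regime in which the pipeline's claims are tested.
* **HEAR** maps each channel's sliding-window (0.25 s) variance ratio
  against its calibration variance to an artifact probability through a
  linear ramp `p = clip((ratio − 1)/(r_sat − 1), 0, 1)` with saturation
  `r_sat = 5`, so a ratio of 3 — the anchor point such methods quote —
  gives p = 0.5; output is the p-weighted blend with the mean of the
  4 nearest electrodes. The ramp and window are this package's choices;
  only the ratio-3 anchor is externally fixed.
* **Notch frequency** is 50 Hz (European mains).
* The cursor trace is upsampled to 200 Hz before onset detection, the
  common rate all streams are brought to; the 63-tap triangular smoother
  then spans 0.315 s. At the cursor's native 60 Hz the same smoother
  spans over a second and the tangent refinement degrades several-fold.

## Behavioral events

Movement onset: baseline (mean of the last 1 s of the preparation period)
subtracted; first crossing of 0.05 as initial estimate; within the
preceding 1.75 s of the smoothed trace, the finite-difference derivative
(central differences, forward/backward at the edges, earliest maximum on
ties) defines a tangent whose zero crossing is the final onset. Offset:
first time the distance to target drops below 0.1. The tangent method has
a small intrinsic late bias that grows with movement duration (~30 ms at
the 0.49 s grand-average duration, noiseless); this is a property of the
algorithm itself, not of its implementation, and the tests bound it at
50 ms for typical durations. The measured movement durations are likewise
systematically shorter than the kinematic ground truth (the offset rule
fires when the remaining distance drops below 0.1, i.e. at ~83% of the
minimum-jerk trajectory), so behavioral statistics compare like with like
across conditions rather than recovering the latent duration. Outlier trials are flagged at 2.5 robust SDs
(median and 1.4826 × MAD) on onset-relative-to-trial-start or duration.
Group behavior uses a two-way repeated-measures ANOVA
(condition × direction) via `aov` with subject error strata, uncorrected
degrees of freedom (no sphericity correction), and Bonferroni-corrected
post-hoc paired t-tests.

Eye-movement onsets come from the trial-averaged EOG derivatives
(horizontal: right minus left outer canthus; vertical: superior minus
inferior, averaged over eyes): the first time the direction-associated
signed derivative exceeds the 1–1.5 s baseline mean by 3 SDs *and stays
above it for at least 25 ms* — the sustained-crossing requirement
suppresses single-sample noise crossings that a bare threshold produces
with high probability over a multi-second scan.

## Epoching and artifact rejection

Broadband epochs are cut under the half-open convention `[a, b)` — at
10 Hz, [0.75, 4.75) s gives 40 samples and [−2, 1.25) s gives 32. The
rejection applies ±200 µV amplitude plus three per-channel statistics
(joint probability, kurtosis, variance) at 6/6/5 robust SDs across
trials, **twice** — statistics are recomputed on first-pass survivors so
subtle outliers unmasked by gross ones are caught. The joint-probability
statistic is the negative mean Gaussian log-density of the epoch under
the channel's all-trial distribution: a deterministic stand-in for
kernel-density variants, chosen for testability. Robust (median/MAD)
centering is used throughout, consistent with the outlier rule above. The
union mask is applied to the delta-band epochs.

## Encoding model

For each time-point, `X(i) = A(i) S + E(i)` with the 4 × n design
`S = [s_cond; s_horz; s_vert; 1]` (condition exe/obs = ±1; direction split
into orthogonal horizontal/vertical factors ±1/0; cells equalized to the
minimum count by seeded subsampling; factors z-scored), solved as
`Â(i) = C_XS(i) C_SS⁻¹` with the 4 × 4 factor covariance estimated by
analytic (Ledoit-Wolf) shrinkage toward a scaled identity — the simplest
admissible target; with z-scored factors the intercept coefficients are
the across-trial mean (exactly so when shrinkage is disabled, to within
the small shrinkage perturbation otherwise). Residual diagnostics are
emitted as per-channel skewness, excess kurtosis and residual-vs-fitted
correlation rather than plots, so they can be asserted.

## Source imaging

sLORETA: minimum-norm kernel `W = Lᵀ(L Lᵀ + λ²C)⁻¹` (noise covariance
`C` from the calibration rest half, shrunk by 10 % of its average
eigenvalue) standardized by the inverse square root of each voxel's 3 × 3
resolution block. Validation deliberately commits the *inverse crime* —
the simulation leadfield is the imaging leadfield — because the target is
pipeline correctness (zero localization error for noiseless dipoles,
verified by brute-force voxel scans), not imaging realism; a
noise-perturbed-leadfield mode covers robustness. Source values are
normalized by a single per-subject GFP constant: the median over
repetitions (study setting 10,000) of the SD across source components of
the average of one random sample per trial, applied to activity and
coefficients alike. Direction information per voxel is the sum of the
horizontal- and vertical-factor orientation norms.

## Decoding

Shrinkage-LDA with the same analytic shrinkage estimator for the pooled
within-class covariance; multi-class via shared-covariance class scores
and arg-max — the standard construction consistent with the two-class
description. Leave-one-trial-out cross-validation gives exactly N folds
with each trial tested once. Features are either the 64 channels at one
time-point or the channels at the current and 5 preceding time-points
(384 features). Significance levels per subject are the 95th percentile
of label-shuffle accuracies (study setting 1000 shuffles). Peak
accuracies are searched within the cue-to-movement-offset interval, and
alignment differences are tested with paired permutation t-tests.
Equalizing direction trial counts before direction CV is available as an
option and off by default.

## Permutation statistics

Group maps use sign-flip permutation tests (subject effects randomly
negated before averaging and norm extraction); pairwise comparisons use
sign-flipped paired t statistics. Sign-flip nulls have only \(2^S\)
distinct patterns for \(S\) subjects, so with the desk-scale cohorts used
here (4–6 subjects) the attainable p-values are coarse
(\(p \ge 1/2^S\) before smoothing) and voxel-level FDR significance is
structurally out of reach — the pipeline reports peak locations and
counts, and reaches conventional significance only at study-scale cohort
sizes (the study has 15 subjects). Sampled permutation p-values use the
+1-smoothed estimator `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, which
cannot return zero and differs from the unsmoothed fraction by at most
1/n_perm; exhaustive enumeration (used in the tests up to 2⁵ patterns)
returns exact fractions. FDR control is Benjamini–Hochberg over a single
pooled family by default, with the family composition logged.

## Problem sizes

The package's own runs use desk-scale sizes, chosen as the smallest
cohorts in which every qualitative effect is stable: the analysis scripts
process one 120-trial subject (150 voxels) and a 5-subject group at 96
trials each; the test suite's end-to-end cohort is 4 subjects × 96 trials
× 120 voxels with 300 GFP repetitions and 500 permutations. The study
conditions themselves (360 trials, 15 subjects, 10,000 permutations and
GFP repetitions, 1000 shuffles) remain the defaults of `synth_config()`
and `pipeline_config()`.

## What passing tests do and do not show

The generator produces linear mixing, Gaussian pink noise, exactly
minimum-jerk kinematics, artifact contamination that is linear in the
EOG-derived sources, and stationary backgrounds. Real recordings violate
all of these to some degree: muscle and movement artifacts are not
low-rank, eye artifacts include saccadic spike potentials (out of scope
here), heads are not spheres, electrodes move. Passing this suite
therefore certifies the *analysis machinery* — filters, detectors,
estimators, tests, and their interactions — under the assumptions the
methods themselves make; it does not certify imaging accuracy on real
anatomy, nor that effect sizes on real data will match the calibrated
synthetic ones. Mauchly's sphericity test, ICA-based rejection and
cluster-based permutation corrections are deliberately out of scope.
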