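# deltamotor

Delta-band (< 3 Hz) EEG analysis of hand-movement initiation and
directional processing during center-out reaching, built as a fully tested,
reusable pipeline over synthetic recordings with known ground truth.

## The problem

In a visually guided center-out task with an execution condition (move eyes
and arm) and an observation condition (move eyes only), two processes shape
low-frequency EEG:

* **movement initiation** — the movement-related cortical potential (MRCP),
  a slow negativity over central sensorimotor cortex phase-locked to the
  movement onset (≈ −2.3 µV in execution, ≈ −0.7 µV in observation at the
  central contralateral channel);
* **directional processing** — parieto-occipital activity phase-locked to
  the direction cue, 300–400 ms after it.

Disentangling them requires the same trials analyzed under two alignments
(trial start vs. detected movement onset), a per-timepoint linear encoding
model, distributed source imaging, and single-trial decoding. `deltamotor`
implements the whole chain for researchers who want to study, extend or
stress-test this analysis style with full ground-truth control:

1. **synthetic experiments** — 64 EEG + 6 EOG channels at 200 Hz, cursor
   distance at 60 Hz, 360 trials (2 conditions × 4 directions), condition
   cue at 2.0 s, direction cue at 2.5 s, movement onsets ~ N(3.23, 0.18²) s;
   single-sphere analytic leadfield; MRCP, visual and cosine direction-tuned
   sources; spatially correlated pink noise; EOG-driven eye artifacts; a
   calibration recording (rest + scripted blinks/saccades);
2. **preprocessing** — 0.4 Hz high-pass + 50 Hz notch (zero-phase 4th-order
   Butterworth), spherical-spline interpolation, calibration-fitted
   eye-artifact regression, common average reference, HEAR transient
   removal, 3 Hz low-pass, resampling to 10 Hz;
3. **behavior** — threshold + tangent-refinement cursor onset detection,
   robust (median/1.4826·MAD, 2.5 SD) outlier flagging, EOG saccade onsets,
   two-way repeated-measures ANOVA;
4. **epoching & QC** — [0.75, 4.75) s and [−2, 1.25) s windows; ±200 µV and
   two-pass joint-probability / kurtosis / variance rejection (6/6/5 robust
   SDs);
5. **encoding** — per-timepoint GLM `X(i) = A(i)·S + E(i)` with
   `S = [s_cond; s_horz; s_vert; 1]`, solved as `Â = C_XS · C_SS⁻¹` with
   analytic (Ledoit–Wolf) shrinkage of `C_SS`;
6. **source imaging** — sLORETA over the simulation leadfield, noise
   covariance shrunk by 10% of its average eigenvalue, global-field-power
   normalization (median over random single-sample-per-trial averages),
   per-voxel orientation norms and the horizontal+vertical direction map;
7. **decoding** — shrinkage-LDA (2-class condition, 4-class direction),
   leave-one-trial-out CV, single-timepoint or windowed (64 × 6 = 384)
   features, label-shuffle significance levels (95th percentile);
8. **group statistics** — sign-flip permutation tests, paired permutation
   t-tests (8 ROIs × 2 alignments = 16 ROI condition-difference tests),
   Benjamini–Hochberg FDR.

## Worked example

Generate a subject, preprocess, detect behavior, and decode:

```r
library(deltamotor)

cfg <- synth_config(n_trials = 120, n_voxels = 150)
gen <- generate_experiment(cfg, seed = 1)
pre <- preprocess_recording(gen$eeg, gen$calibration,
                            gen$leadfield$channel_positions)
trials <- detect_trial_events(gen$cursor, gen$trials)

keep <- which(!trials$outlier)
ep <- extract_epochs(pre$delta, trials$t_trial_start[keep],
                     c(0.75, 4.75), band = "delta")
cv <- crossval_accuracy_curve(ep, trials$condition[keep],
                              interval = c(2, 4))
max(cv$accuracy, na.rm = TRUE)
```

Running the numbered drivers in `analysis/` reproduces the full workflow
and writes tab-separated tables under `results/`. On this synthetic subject
(`Rscript analysis/02_preprocess_behavior.R`):

```
detected onset: 3.266 s (0.168 SD); duration 0.352 s (0.068 SD); 3/120 outliers
eye-movement onsets (s):
right    up  left  down
2.695 2.700 2.695 2.700
```

The detected onsets sit ≈ 30 ms after the ground-truth minimum-jerk onsets
(the tangent method's intrinsic bias) and the catch-up saccade lands at
the generator's 2.69 s. `analysis/04_decoding.R` prints, for this subject:

```
      alignment condition_peak condition_peak_time condition_shuffle_threshold
    trial_start          0.885                3.05                       0.593
 movement_onset          0.991               -0.20                       0.589
 direction_peak direction_peak_time windowed_exe_peak
          0.434                2.95             0.463
          0.321               -1.20             0.340
```

— condition decoding peaks at the movement onset, and the 4-class
direction accuracy is far higher cue-aligned (0.434 at 2.95 s) than
movement-aligned (0.321): the central qualitative effect.
`analysis/05_group_analysis.R` runs a 6-subject group: the
repeated-measures ANOVAs (all null, as simulated), the 16 ROI
condition-difference tests, the source-space peaks — the condition factor
peaks in left primary sensorimotor cortex at 2.95 s (trial-aligned) and
−0.2 s (movement-aligned), and the parieto-occipital direction-norm curve
peaks at 2.75 s, shortly after the direction cue — and the paired
alignment comparison of windowed direction-decoding peaks (cue-aligned
mean 0.393 vs movement-aligned 0.337 at this cohort size).

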