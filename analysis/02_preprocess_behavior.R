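#!/usr/bin/env Rscript

# Preprocess the subject generated in 01 (same seed regenerates it
# deterministically), detect cursor movement onsets/offsets, flag outlier
# trials, and detect the direction-specific eye-movement onsets. Writes
# results/02_behavior_cells.tsv, results/02_eye_onsets.tsv and
# results/02_onset_accuracy.tsv.

suppressMessages(library(deltamotor))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(n_trials = 120, n_voxels = 150)
gen <- generate_experiment(cfg, seed = 1)
pre <- preprocess_recording(gen$eeg, gen$calibration,
                            gen$leadfield$channel_positions)
trials <- detect_trial_events(gen$cursor, gen$trials)
write_trial_events(trials, "results/02_events_detected.tsv")

ok <- !trials$outlier
onset_rel <- trials$detected_onset - trials$t_trial_start
cat(sprintf("detected onset: %.3f s (%.3f SD); duration %.3f s (%.3f SD); %d/%d outliers\n",
            mean(onset_rel[ok]), sd(onset_rel[ok]),
            mean(trials$duration[ok]), sd(trials$duration[ok]),
            sum(!ok), nrow(trials)))

err <- abs(trials$detected_onset - trials$truth_move_onset)[ok]
acc <- data.frame(quantity = c("mean_abs_onset_error_ms",
                               "median_abs_onset_error_ms",
                               "n_outliers"),
                  value = round(c(1000 * mean(err), 1000 * median(err),
                                  sum(!ok)), 2))
write.table(acc, "results/02_onset_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cells <- expand.grid(condition = c("exe", "obs"),
                     direction = c("right", "up", "left", "down"),
                     stringsAsFactors = FALSE)
cells$onset_mean <- NA
cells$duration_mean <- NA
for (i in seq_len(nrow(cells))) {
  sel <- ok & trials$condition == cells$condition[i] &
    trials$direction == cells$direction[i]
  cells$onset_mean[i] <- mean(onset_rel[sel])
  cells$duration_mean[i] <- mean(trials$duration[sel])
}
write.table(cells, "results/02_behavior_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

eye <- detect_eye_onset(pre$broadband, trials)
write.table(data.frame(direction = names(eye), onset_s = round(eye, 4)),
            "results/02_eye_onsets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("eye-movement onsets (s):\n")
print(round(eye, 3))
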