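#!/usr/bin/env Rscript

# Single-trial decoding for the subject from 01: condition (2-class) and
# direction (4-class) sLDA accuracy curves with leave-one-trial-out CV for
# both alignments, a label-shuffling significance level, and the windowed
# direction classifier used for the alignment comparison.
# Writes results/04_accuracy_curves.tsv and results/04_decoding_summary.tsv.

suppressMessages(library(deltamotor))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(n_trials = 120, n_voxels = 150)
gen <- generate_experiment(cfg, seed = 1)
pre <- preprocess_recording(gen$eeg, gen$calibration,
                            gen$leadfield$channel_positions)
trials <- detect_trial_events(gen$cursor, gen$trials)
keep0 <- which(!trials$outlier & !is.na(trials$detected_onset))

process <- function(anchors, window, tag) {
  bb <- extract_epochs(pre$broadband, anchors, window, alignment = tag)
  rej <- reject_artifact_epochs(bb)
  dl <- extract_epochs(pre$delta, anchors, window, alignment = tag,
                       band = "delta")
  kept <- drop_rejected(apply_rejection(dl, rej$mask))
  list(epochs = kept$epochs, trials = trials[keep0[kept$index], ])
}
al <- list(
  trial_start = process(trials$t_trial_start[keep0], c(0.75, 4.75),
                        "trial_start"),
  movement_onset = process(trials$detected_onset[keep0], c(-2, 1.25),
                           "movement_onset"))
intervals <- list(trial_start = c(2.0, 4.0), movement_onset = c(-1.2, 0.8))

curves <- list()
summary_rows <- list()
for (tag in names(al)) {
  a <- al[[tag]]
  iv <- intervals[[tag]]
  cc <- crossval_accuracy_curve(a$epochs, a$trials$condition, interval = iv)
  dd <- crossval_accuracy_curve(a$epochs, a$trials$direction, interval = iv)
  exe <- which(a$trials$condition == "exe")
  ep_exe <- new_epochs(a$epochs$data[exe, , , drop = FALSE], a$epochs$time,
                       a$epochs$fs, a$epochs$alignment, a$epochs$band)
  dw <- crossval_accuracy_curve(ep_exe, a$trials$direction[exe],
                                mode = "windowed", interval = iv)
  thr <- shuffle_significance_level(a$epochs, a$trials$condition,
                                    n_shuffles = 100,
                                    time_subset = which(
                                      a$epochs$time >= iv[1] &
                                        a$epochs$time <= iv[2])[c(TRUE,
                                                                  FALSE)],
                                    seed = 17)$threshold
  curves[[tag]] <- data.frame(
    alignment = tag, time = cc$time,
    condition = round(cc$accuracy, 4), direction = round(dd$accuracy, 4),
    direction_exe_windowed = round(dw$accuracy, 4))
  summary_rows[[tag]] <- data.frame(
    alignment = tag,
    condition_peak = max(cc$accuracy, na.rm = TRUE),
    condition_peak_time = cc$time[which.max(cc$accuracy)],
    condition_shuffle_threshold = thr,
    direction_peak = max(dd$accuracy, na.rm = TRUE),
    direction_peak_time = dd$time[which.max(dd$accuracy)],
    windowed_exe_peak = max(dw$accuracy, na.rm = TRUE))
}
write.table(do.call(rbind, curves), "results/04_accuracy_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
summary <- do.call(rbind, summary_rows)
write.table(summary, "results/04_decoding_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary, row.names = FALSE, digits = 3)
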