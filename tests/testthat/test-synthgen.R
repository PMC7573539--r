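test_that("trial tables are balanced with exact cue timing", {
  tt <- build_trial_table(360, synth_config(), seed = 1)
  expect_equal(tt$t_condition_cue - tt$t_trial_start, rep(2.0, 360))
  expect_equal(tt$t_direction_cue - tt$t_trial_start, rep(2.5, 360))
  cells <- table(tt$condition, tt$direction)
  expect_true(all(cells == 45))
  expect_equal(sum(tt$condition == "exe"), 180)

  t8 <- build_trial_table(8, synth_config(), seed = 2)
  expect_true(all(table(t8$condition, t8$direction) == 1))

  # remainder rule: cell counts differ by at most one
  t13 <- build_trial_table(13, synth_config(), seed = 3)
  expect_true(max(table(t13$condition, t13$direction)) -
                min(table(t13$condition, t13$direction)) <= 1)
  expect_error(build_trial_table(5, synth_config()), ">= 8")
})

test_that("same config and seed give identical experiments", {
  cfg <- synth_config(n_trials = 8, n_voxels = 80, calib_duration = 20)
  a <- generate_experiment(cfg, seed = 9)
  b <- generate_experiment(cfg, seed = 9)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$cursor$data, b$cursor$data)
  expect_identical(a$trials, b$trials)
  expect_identical(a$calibration$data, b$calibration$data)
})

test_that("EEG equals projected sources + noise + contamination exactly", {
  gen <- small_experiment()
  eeg <- gen$eeg$data[gen$eeg$channel_types == "eeg", ]
  resum <- gen$components$clean + gen$components$noise +
    gen$components$contamination
  expect_identical(eeg, resum)
})

test_that("trial sources respect condition scaling and direction tuning", {
  gen <- small_experiment()
  cfg <- gen$config
  tr <- gen$trials
  right <- tr[tr$direction == "right", ][1, ]
  left <- right
  left$direction <- "left"
  s_r <- simulate_trial_sources(right, cfg, prep = gen$prep)
  s_l <- simulate_trial_sources(left, cfg, prep = gen$prep)
  po_rows <- as.vector(vapply(gen$prep$po_idx,
                              function(v) (3 * v - 2):(3 * v),
                              integer(3)))
  other <- setdiff(seq_len(nrow(s_r$sources)), po_rows)
  # PO direction component sign-flips between opposite directions (cosine
  # tuning), everything else (MRCP, visual responses) identical
  expect_equal(s_r$sources[other, ], s_l$sources[other, ], tolerance = 1e-12)
  expect_equal(s_l$sources[po_rows, ], -s_r$sources[po_rows, ],
               tolerance = 1e-12)
  expect_gt(max(abs(s_r$sources[po_rows, ])), 0)
  expect_error(simulate_trial_sources(transform(right, direction = "diag"),
                                      cfg, prep = gen$prep), "direction")
})

test_that("projected MRCP peaks match the configured channel targets", {
  gen <- small_experiment()
  lf <- gen$leadfield
  cc <- gen$prep$central_channel
  tr <- gen$trials
  peak_for <- function(cond) {
    row <- tr[tr$condition == cond, ][1, ]
    s <- simulate_trial_sources(row, gen$config, prep = gen$prep)
    proj <- lf$gain %*% s$sources
    on_rel <- row$truth_move_onset - row$t_trial_start
    proj[cc, which.min(abs(s$time - (on_rel - 0.1)))]
  }
  # -2.3 uV in execution; about 0.3 x that in observation (visual responses
  # overlap slightly at the central channel)
  expect_equal(peak_for("exe"), -2.3, tolerance = 0.05)
  expect_equal(peak_for("obs"), -0.7, tolerance = 0.1)
})

test_that("cursor traces follow the minimum-jerk profile", {
  # grand-average duration: trace reaches 1 exactly at onset + duration
  tr <- simulate_cursor_trajectory("right", onset = 3.2, duration = 0.49,
                                   fs = 60, noise_sd = 0)
  i_done <- which(tr$time >= 3.2 + 0.49)[1]
  expect_equal(tr$distance[i_done], 1)
  expect_true(all(tr$distance[tr$time < 3.2] == 0))
  expect_true(all(diff(tr$distance[tr$time >= 3.2 & tr$time <= 3.69]) >= 0))

  # threshold crossing of the noiseless trace matches the analytic root
  root <- uniroot(function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5 - 0.05,
                  c(1e-6, 1))$root
  t_cross <- tr$time[which(tr$distance > 0.05)[1]]
  expect_lt(abs(t_cross - (3.2 + root * 0.49)), 1 / 60 + 1e-9)
  expect_error(simulate_cursor_trajectory("right", 1, -0.1), "duration")
})

test_that("eye-artifact sign conventions and gain contract hold", {
  lf <- tiny_leadfield()
  n <- 400
  gh <- c(rep(0, 200), rep(1, 200))  # rightward saccade
  gv <- rep(0, n)
  ea <- simulate_eye_artifacts(gh, gv, blink_times = numeric(), fs = 200,
                               lf = lf, gain = 1)
  hderiv <- ea$eog["EOG-ro", ] - ea$eog["EOG-lo", ]
  expect_true(all(hderiv[201:400] > 0))
  ea0 <- simulate_eye_artifacts(gh, gv, numeric(), 200, lf, gain = 0)
  expect_true(all(ea0$contamination == 0))
  # blinks deflect the vertical derivatives upward
  eb <- simulate_eye_artifacts(rep(0, n), rep(0, n), blink_times = 1,
                               fs = 200, lf = lf)
  vderiv <- eb$eog["EOG-ls", ] - eb$eog["EOG-li", ]
  expect_gt(max(vderiv), 0)
})

test_that("clean source waveforms are delta-band dominated", {
  # >= 95% of spectral energy below 3 Hz for each waveform template
  fs <- 200
  t <- seq(0, 7 - 1 / fs, by = 1 / fs)
  frac_below <- function(w, f_cut = 3) {
    sp <- Mod(fft(w))^2
    f <- (seq_along(w) - 1) * fs / length(w)
    f <- pmin(f, fs - f)
    sum(sp[f < f_cut]) / sum(sp)
  }
  expect_gt(frac_below(deltamotor:::.mrcp_wave(t, 3.2)), 0.95)
  expect_gt(frac_below(deltamotor:::.vep_wave(t, 2.0)), 0.95)
  expect_gt(frac_below(deltamotor:::.dir_wave(t, 2.5)), 0.95)
})
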