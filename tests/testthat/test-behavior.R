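test_that("onset detection is exact on gentle linear ramps", {
  fs <- 200
  t <- seq(0, 6, by = 1 / fs)
  for (slope in c(0.04, 0.08)) {
    t0 <- 3.0
    d <- pmax(0, t - t0) * slope
    got <- detect_cursor_events(d, fs)
    expect_true(got$moved)
    expect_lt(abs(got$onset - t0), 1 / fs + 1e-9)
    # baseline invariance: adding a constant offset changes nothing
    got_b <- detect_cursor_events(d + 0.3, fs)
    expect_equal(got_b$onset, got$onset, tolerance = 1e-9)
  }
})

test_that("onset detection is accurate on minimum-jerk traces at 60 Hz", {
  fs <- 60
  t <- seq(0, 6, by = 1 / fs)
  for (dur in c(0.36, 0.49, 0.55)) {
    d <- minimum_jerk(t, 3.23, dur)
    got <- detect_cursor_events(d, fs)
    expect_lt(abs(got$onset - 3.23), 0.05)
    # offset: first crossing of distance-to-target < 0.1
    root9 <- uniroot(function(x) 10 * x^3 - 15 * x^4 + 6 * x^5 - 0.9,
                     c(0.5, 1))$root
    expect_lt(abs(got$offset - (3.23 + root9 * dur)), 2 / fs)
  }
})

test_that("onset detector is translation-equivariant and flags no-movement", {
  fs <- 60
  t <- seq(0, 8, by = 1 / fs)
  d <- minimum_jerk(t, 3.2, 0.5)
  base <- detect_cursor_events(d, fs)
  shift <- 30 / fs  # exact sample multiple
  d2 <- minimum_jerk(t, 3.2 + shift, 0.5)
  p2 <- onset_params(t_prep_end = 2.5 + shift)
  got <- detect_cursor_events(d2, fs, p2)
  expect_equal(got$onset - base$onset, shift, tolerance = 1e-6)

  flat <- detect_cursor_events(rep(0.01, length(t)), fs)
  expect_false(flat$moved)
  expect_true(is.na(flat$onset))
})

test_that("robust outlier flagging matches the Gaussian tail rate", {
  expect_error(flag_outlier_trials(c(1, 2), c(1, 2)), "3 trials")
  n <- 20
  expect_false(any(flag_outlier_trials(rep(3, n), rep(0.5, n))))
  on <- c(rep(3, n), 10)
  expect_true(flag_outlier_trials(on, rep(0.5, n + 1))[n + 1])

  set.seed(99)
  x <- rnorm(1e5)
  mask <- flag_outlier_trials(x, rep(1, 1e5), k = 2.5)
  expect_lt(abs(mean(mask) - 2 * pnorm(-2.5)), 0.001)
})

test_that("eye-movement onsets are detected from EOG derivatives", {
  lf <- tiny_leadfield()
  fs <- 200
  n_tr <- 8
  len <- 5 * fs
  dirs <- rep(c("right", "left", "up", "down"), 2)
  step_at <- 2.7
  gh <- gv <- numeric(n_tr * len)
  for (i in seq_len(n_tr)) {
    idx <- ((i - 1) * len + round(step_at * fs)):(i * len)
    if (dirs[i] == "right") gh[idx] <- 1
    if (dirs[i] == "left") gh[idx] <- -1
    if (dirs[i] == "up") gv[idx] <- 1
    if (dirs[i] == "down") gv[idx] <- -1
  }
  eye <- simulate_eye_artifacts(gh, gv, numeric(), fs, lf)
  nch <- nrow(lf$channel_positions)
  rec <- new_recording(rbind(matrix(0, nch, n_tr * len), eye$eog), fs,
                       c(sprintf("C%02d", 1:nch), rownames(eye$eog)),
                       c(rep("eeg", nch), rep("eog", 6)))
  trials <- data.frame(t_trial_start = (seq_len(n_tr) - 1) * 5,
                       direction = dirs)
  on <- detect_eye_onset(rec, trials)
  # noiseless step: detected at the step sample for every direction
  expect_true(all(abs(on - step_at) <= 1 / fs + 1e-9))

  flat <- new_recording(matrix(0, nch + 6, n_tr * len), fs,
                        rec$channel_names, rec$channel_types)
  expect_true(all(is.na(detect_eye_onset(flat, trials))))
})

test_that("generated catch-up saccades are detected near 2.69 s", {
  px <- prepped_experiment()
  on <- detect_eye_onset(px$pre$broadband, px$trials)
  expect_true(all(abs(on - 2.69) < 0.05))
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 2 subjects x 2 conditions x 4 directions, worked by hand below
  v <- array(c(1, 2, 3, 5, 2, 3, 4, 6, 3, 4, 5, 7, 4, 5, 6, 8),
             dim = c(2, 2, 4),
             dimnames = list(NULL, c("exe", "obs"), NULL))
  res <- rm_anova_two_way(v)$anova
  # condition effect: SS_cond with 1 df against subject x condition
  m <- apply(v, c(1, 2), mean)          # subject x condition means
  gm <- mean(v)
  ss_cond <- 4 * sum((colMeans(m) - gm)^2) * 2 / 2 * 2
  # compute via standard formulas
  nd <- 4
  ss_cond <- 2 * nd * sum((apply(v, 2, mean) - gm)^2)
  ss_subj <- 2 * nd * sum((apply(v, 1, mean) - gm)^2)
  inter <- m - outer(rowMeans(m), rep(1, 2)) -
    outer(rep(1, 2), colMeans(m)) + gm
  ss_sc <- nd * sum(inter^2)
  f_cond <- (ss_cond / 1) / (ss_sc / 1)
  expect_equal(res$F[res$effect == "condition"], f_cond, tolerance = 1e-10)
})

test_that("ANOVA type-I error and power behave as expected", {
  set.seed(7)
  reps <- 300
  pc <- replicate(reps, {
    v <- array(rnorm(10 * 2 * 4) + rep(rnorm(10), 8), dim = c(10, 2, 4))
    rm_anova_two_way(v)$anova$p[1]
  })
  expect_lt(abs(mean(pc < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(pc, "punif")$p.value), 0.01)

  v <- array(rnorm(10 * 2 * 4, sd = 0.1), dim = c(10, 2, 4))
  v[, 2, ] <- v[, 2, ] + 3  # condition shift far above the noise
  expect_lt(rm_anova_two_way(v)$anova$p[1], 0.001)

  v[1, 1, 1] <- NA
  expect_error(rm_anova_two_way(v), "missing")
})

test_that("trial-level detection feeds the trial table and events file", {
  px <- prepped_experiment()
  tr <- px$trials
  ok <- !tr$outlier
  err <- abs(tr$detected_onset - tr$truth_move_onset)[ok]
  expect_lt(mean(err), 0.06)
  expect_true(all(tr$duration[ok] > 0.1 & tr$duration[ok] < 1.5))

  path <- file.path(tempdir(), "events.tsv")
  write_trial_events(tr, path)
  back <- read_events_tsv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_true(all(abs(back$onset - tr$t_trial_start) < 1e-3))
  expect_equal(back$bad_trial, tr$outlier)
})
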