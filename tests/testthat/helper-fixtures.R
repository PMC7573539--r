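# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

tiny_leadfield <- function() {
  fixture("tiny_leadfield", build_leadfield(32, 80, seed = 42))
}

small_experiment <- function() {
  fixture("small_experiment", generate_experiment(
    synth_config(n_trials = 16, n_voxels = 100, calib_duration = 60),
    seed = 101, return_components = TRUE))
}

# a preprocessed mid-size experiment shared by behavior / epoching tests
prepped_experiment <- function() {
  fixture("prepped_experiment", {
    gen <- generate_experiment(
      synth_config(n_trials = 48, n_voxels = 100, calib_duration = 120),
      seed = 202)
    pre <- preprocess_recording(gen$eeg, gen$calibration,
                                gen$leadfield$channel_positions)
    trials <- detect_trial_events(gen$cursor, gen$trials)
    list(gen = gen, pre = pre, trials = trials)
  })
}

# small cohort driving the end-to-end qualitative checks; sizes are the
# desk-scale study conditions used throughout the package documentation
cohort_config <- function() {
  pipeline_config(
    n_subjects = 4L,
    synth = synth_config(n_trials = 96, n_voxels = 120),
    n_perm = 500L, gfp_reps = 300L)
}

cohort_subjects <- function() {
  fixture("cohort_subjects", {
    cfg <- cohort_config()
    lapply(seq_len(cfg$n_subjects), function(s) {
      run_subject(cfg, seed = 7000L + 113L * s)
    })
  })
}
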