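#' @title Synthetic center-out EEG experiment generator
#' @description
#' Emulates the recordings the analysis pipeline expects: 64 EEG + 6 EOG
#' channels at 200 Hz, a normalized cursor-distance trace at 60 Hz, 360
#' trials in 2 conditions (execution / observation) x 4 directions, with the
#' condition cue at 2.0 s and the direction cue at 2.5 s of each trial, plus
#' a calibration recording (rest followed by scripted blinks and saccades).
#' Neural activity is mixed into the channels through the single-sphere
#' leadfield: a movement-related cortical potential (MRCP) in sensorimotor
#' voxels phase-locked to the (ground-truth) movement onset, visually evoked
#' responses in occipital voxels after both cues, and a cosine direction-tuned
#' parieto-occipital response phase-locked to the direction cue. Pink
#' spatially correlated noise and EOG-driven eye-artifact contamination are
#' added on top. Every trial stores its ground-truth movement onset.
#' @name synthgen
NULL

.DIR_LEVELS <- c("right", "up", "left", "down")
.DIR_ANGLE <- c(right = 0, up = pi / 2, left = pi, down = 3 * pi / 2)

#' Default generator configuration
#'
#' All timing and amplitude defaults are the study conditions the pipeline
#' is designed for: 360 trials, cues at 2.0 / 2.5 s, movement onsets drawn
#' from a truncated Normal(3.23, 0.18) s, movement durations from
#' Normal(0.49, 0.13) s, an execution-condition MRCP peaking at -2.3 uV on
#' the central contralateral channel (observation scaled by 0.3, i.e.
#' about -0.7 uV), and a 190 ms catch-up saccade after the direction cue.
#'
#' @param n_trials total number of trials (>= 8; balanced over the 8
#'   condition x direction cells, remainder cells chosen in seeded order).
#' @param n_channels,n_voxels leadfield size.
#' @param fs EEG/EOG sampling rate, Hz.
#' @param fs_cursor cursor sampling rate, Hz.
#' @param trial_period seconds allotted per trial (recording is contiguous).
#' @param mrcp_peak execution-condition MRCP channel-space peak, uV
#'   (negative).
#' @param obs_scale observation-condition MRCP scale factor.
#' @param vep_peak visually-evoked response channel-space peak, uV.
#' @param dir_peak direction-tuned parieto-occipital channel-space peak, uV.
#' @param onset_mean,onset_sd,onset_range movement-onset distribution
#'   (seconds from trial start; truncated normal).
#' @param dur_mean,dur_sd,dur_range movement-duration distribution, s.
#' @param saccade_latency catch-up saccade latency after the direction cue, s.
#' @param noise_sd per-channel pink-noise standard deviation, uV.
#' @param artifact_gain global scale of the eye-artifact contamination
#'   (0 disables it).
#' @param cursor_noise_sd baseline jitter of the cursor distance trace.
#' @param calib_duration calibration recording length, s (rest in the first
#'   half, scripted blinks and saccades in the second half).
#' @return configuration list for [generate_experiment()].
#' @export
synth_config <- function(n_trials = 360L, n_channels = 64L, n_voxels = 200L,
                         fs = 200, fs_cursor = 60, trial_period = 7,
                         mrcp_peak = -2.3, obs_scale = 0.3,
                         vep_peak = 3, dir_peak = 0.3,
                         onset_mean = 3.23, onset_sd = 0.18,
                         onset_range = c(2.7, 4.0),
                         dur_mean = 0.49, dur_sd = 0.13,
                         dur_range = c(0.25, 0.9),
                         saccade_latency = 0.19,
                         noise_sd = 2, artifact_gain = 1,
                         cursor_noise_sd = 0.008,
                         calib_duration = 300,
                         leadfield_seed = 7777L) {
  as.list(environment())
}

# truncated normal draws by rejection (ranges are wide; acceptance is high)
.rtnorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < range[1] | x > range[2])
  }
  x
}

# --- smooth sub-3 Hz waveform templates (unit peak) ---------------------

# MRCP: Gaussian rise to a peak 100 ms before the movement onset, then
# exponential decay, softened by a short Gaussian kernel so that >= 95% of
# the energy stays below 3 Hz
.mrcp_wave <- function(t, onset, rise_sd = 0.40, decay_tau = 0.45,
                       smooth_sd = 0.08) {
  tp <- onset - 0.1
  w <- ifelse(t <= tp, exp(-(t - tp)^2 / (2 * rise_sd^2)),
              exp(-(t - tp) / decay_tau))
  .gauss_smooth(w, t, smooth_sd)
}

# VEP: Gaussian-windowed slow cycle ~150 ms after the cue; f0 and envelope
# chosen so that >= 95% of the energy stays below 3 Hz
.vep_wave <- function(t, cue, f0 = 1.4, sd = 0.2, lat = 0.18) {
  w <- sin(2 * pi * f0 * (t - cue - lat + 0.12)) *
    exp(-(t - cue - lat)^2 / (2 * sd^2))
  w / max(abs(w) + 1e-12)
}

# direction-tuned parieto-occipital bump peaking ~350 ms after the cue
.dir_wave <- function(t, cue, lat = 0.35, sd = 0.15) {
  exp(-(t - cue - lat)^2 / (2 * sd^2))
}

.gauss_smooth <- function(w, t, sd) {
  if (sd <= 0) return(w)
  dt <- t[2] - t[1]
  half <- ceiling(4 * sd / dt)
  k <- stats::dnorm(seq(-half, half) * dt, sd = sd)
  k <- k / sum(k)
  out <- stats::filter(c(rep(w[1], half), w, rep(w[length(w)], half)), k,
                       sides = 2)
  out <- out[(half + 1):(half + length(w))]
  as.numeric(out / max(abs(out) + 1e-12))
}

# --- experiment preparation ---------------------------------------------

# builds the leadfield, voxel roles, preferred directions and amplitude
# calibration so that projected channel-space peaks match the config targets.
# The anatomy (voxel layout) and the direction-tuning map are tied to
# config$leadfield_seed, not the subject seed: a cohort shares one source
# space, as with template-anatomy source imaging
.synth_prepare <- function(config, seed) {
  lf <- build_leadfield(config$n_channels, config$n_voxels,
                        seed = config$leadfield_seed %||% seed)
  nv <- config$n_voxels
  radial <- lf$voxel_positions / sqrt(rowSums(lf$voxel_positions^2))

  pattern_for <- function(vox_idx, weights) {
    p <- numeric(config$n_channels)
    for (k in seq_along(vox_idx)) {
      v <- vox_idx[k]
      p <- p + weights[k] *
        drop(lf$gain[, (3 * v - 2):(3 * v)] %*% radial[v, ])
    }
    p
  }

  sm_l <- which(lf$sim_groups == "SM1-left")
  sm_r <- which(lf$sim_groups == "SM1-right")
  occ <- which(lf$sim_groups == "OCC")
  po <- which(lf$sim_groups %in% c("PO-left", "PO-right"))
  stopifnot(length(sm_l) > 0, length(occ) > 0, length(po) > 0)

  # contralateral (left) sensorimotor sources dominate for right-hand reaches
  sm_idx <- c(sm_l, sm_r)
  sm_w <- c(rep(1, length(sm_l)), rep(0.5, length(sm_r)))
  sm_w <- sm_w / sum(sm_w)
  p_mrcp <- pattern_for(sm_idx, sm_w)
  central_ch <- nearest_channel(lf, c(-0.20, -0.05, 0.98))
  scale_mrcp <- config$mrcp_peak / p_mrcp[central_ch]

  occ_w <- rep(1 / length(occ), length(occ))
  p_vep <- pattern_for(occ, occ_w)
  occ_ch <- nearest_channel(lf, c(0, -0.95, 0.05))
  scale_vep <- config$vep_peak / p_vep[occ_ch]

  po_pref <- .with_seed((config$leadfield_seed %||% seed) + 1L,
                        stats::runif(length(po), 0, 2 * pi))
  p_dir <- lapply(.DIR_LEVELS, function(d) {
    pattern_for(po, cos(.DIR_ANGLE[[d]] - po_pref) / length(po))
  })
  names(p_dir) <- .DIR_LEVELS
  # calibrate by the channel-space maximum over directions: random preferred
  # directions can nearly cancel at any single reference channel
  scale_dir <- config$dir_peak / max(vapply(p_dir, function(p) max(abs(p)), 0))

  list(leadfield = lf, radial = radial,
       sm_idx = sm_idx, sm_w = sm_w, occ_idx = occ, occ_w = occ_w,
       po_idx = po, po_pref = po_pref,
       scales = list(mrcp = scale_mrcp, vep = scale_vep, dir = scale_dir),
       patterns = list(mrcp = p_mrcp * scale_mrcp,
                       vep = p_vep * scale_vep,
                       dir = lapply(p_dir, function(p) p * scale_dir)),
       central_channel = central_ch, occipital_channel = occ_ch)
}

#' Balanced trial table
#'
#' @param n_trials number of trials (>= 8). When not divisible by 8 the
#'   remainder trials are assigned to distinct cells chosen in seeded random
#'   order, so cell counts differ by at most one.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return trial table data.frame (one row per trial, chronological order)
#'   with condition, direction, cue times, ground-truth movement onset and
#'   duration, and empty detection columns.
#' @export
build_trial_table <- function(n_trials, config = synth_config(), seed = 1L) {
  if (n_trials < 8) stop("`n_trials` must be >= 8")
  n_trials <- as.integer(n_trials)
  cells <- expand.grid(condition = c("exe", "obs"), direction = .DIR_LEVELS,
                       stringsAsFactors = FALSE)
  base <- n_trials %/% 8L
  rem <- n_trials %% 8L
  .with_seed(seed, {
    extra <- if (rem > 0) sample.int(8L, rem) else integer()
    counts <- rep(base, 8L) + as.integer(seq_len(8L) %in% extra)
    cond <- rep(cells$condition, counts)
    dir <- rep(cells$direction, counts)
    ord <- sample.int(n_trials)  # pseudo-random trial sequence
    cond <- cond[ord]; dir <- dir[ord]
    onset_rel <- .rtnorm(n_trials, config$onset_mean, config$onset_sd,
                         config$onset_range)
    dur <- .rtnorm(n_trials, config$dur_mean, config$dur_sd,
                   config$dur_range)
  })
  t0 <- (seq_len(n_trials) - 1L) * config$trial_period
  data.frame(
    trial_id = seq_len(n_trials),
    condition = cond, direction = dir,
    t_trial_start = t0,
    t_condition_cue = t0 + 2.0,
    t_direction_cue = t0 + 2.5,
    truth_move_onset = t0 + onset_rel,
    truth_duration = dur,
    truth_saccade = t0 + 2.5 + config$saccade_latency,
    detected_onset = NA_real_, detected_offset = NA_real_,
    duration = NA_real_, outlier = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Source time courses for one trial
#'
#' Returns the full (3 voxels-orientations) x time source matrix for a single
#' trial: the MRCP in sensorimotor voxels (execution amplitude, scaled by
#' `obs_scale` in observation), occipital responses after both cues, and the
#' cosine direction-tuned parieto-occipital component. Amplitudes use the
#' channel-space calibration, so projecting through the leadfield reproduces
#' the configured peaks.
#'
#' @param trial one row of a trial table (needs `condition`, `direction`,
#'   `truth_move_onset`, `t_trial_start`).
#' @param config generator configuration.
#' @param prep internal preparation object; rebuilt from `seed` when NULL.
#' @param seed seed used to rebuild the leadfield when `prep` is NULL.
#' @return list with `sources` ((3 n_voxels) x n_time), `time` (seconds,
#'   trial-relative) and the active voxel indices per component.
#' @export
simulate_trial_sources <- function(trial, config = synth_config(),
                                   prep = NULL, seed = 1L) {
  if (!trial$direction %in% .DIR_LEVELS) {
    stop("unknown direction label: ", trial$direction)
  }
  if (is.null(prep)) prep <- .synth_prepare(config, seed)
  t <- seq(0, config$trial_period - 1 / config$fs, by = 1 / config$fs)
  onset_rel <- trial$truth_move_onset - trial$t_trial_start
  cond_amp <- if (trial$condition == "exe") 1 else config$obs_scale

  w_mrcp <- .mrcp_wave(t, onset_rel) * prep$scales$mrcp * cond_amp
  w_vep <- (.vep_wave(t, 2.0) + .vep_wave(t, 2.5)) * prep$scales$vep
  w_dir <- .dir_wave(t, 2.5) * prep$scales$dir

  nv <- config$n_voxels
  src <- matrix(0, 3 * nv, length(t))
  add_component <- function(src, vox, amp_per_vox, wave) {
    for (k in seq_along(vox)) {
      v <- vox[k]
      rows <- (3 * v - 2):(3 * v)
      src[rows, ] <- src[rows, ] + outer(prep$radial[v, ] * amp_per_vox[k],
                                         wave)
    }
    src
  }
  src <- add_component(src, prep$sm_idx, prep$sm_w, w_mrcp)
  src <- add_component(src, prep$occ_idx, prep$occ_w, w_vep)
  ang <- .DIR_ANGLE[[trial$direction]]
  src <- add_component(src, prep$po_idx,
                       cos(ang - prep$po_pref) / length(prep$po_idx), w_dir)
  list(sources = src, time = t,
       active = list(sm = prep$sm_idx, occ = prep$occ_idx, po = prep$po_idx))
}

#' Minimum-jerk position profile
#'
#' Normalized 0-to-1 minimum-jerk polynomial \eqn{10\tau^3 - 15\tau^4 +
#' 6\tau^5} evaluated at phase \eqn{\tau = (t - onset)/duration}, clamped
#' outside the movement.
#'
#' @param t time vector, s.
#' @param onset movement onset, s.
#' @param duration movement duration, s.
#' @return numeric vector in [0, 1].
#' @export
minimum_jerk <- function(t, onset, duration) {
  tau <- pmin(1, pmax(0, (t - onset) / duration))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Synthetic cursor-distance trace for one reach
#'
#' Euclidean cursor-to-origin distance: near-zero jittery baseline before
#' the movement onset (the resting position is under the participant's
#' control, so the distance is not exactly zero), a minimum-jerk rise to 1
#' over `duration`, then a hold at the target.
#'
#' @param direction direction label (validated; the distance profile itself
#'   is direction-independent).
#' @param onset movement onset, seconds from the start of the trace.
#' @param duration movement duration, s (> 0).
#' @param fs sampling rate, Hz.
#' @param noise_sd baseline jitter standard deviation (smoothed white
#'   noise); 0 gives a noiseless trace.
#' @param t_total trace length, s.
#' @return list with `time`, `distance` and `truth_onset`.
#' @export
simulate_cursor_trajectory <- function(direction = "right", onset, duration,
                                       fs = 60, noise_sd = 0.008,
                                       t_total = onset + duration + 1) {
  if (!direction %in% .DIR_LEVELS) stop("unknown direction label")
  if (duration <= 0) stop("`duration` must be positive")
  t <- seq(0, t_total - 1 / fs, by = 1 / fs)
  d <- minimum_jerk(t, onset, duration)
  if (noise_sd > 0) {
    jit <- stats::rnorm(length(t), sd = noise_sd)
    k <- rep(1 / 9, 9)
    jit <- as.numeric(stats::filter(jit, k, sides = 2, circular = TRUE))
    # jitter reflects resting-hand drift: present before movement only
    d <- d + jit * (1 - d)
  }
  list(time = t, distance = d, truth_onset = onset)
}

#' Eye-artifact model
#'
#' Maps gaze traces and blink events to the six EOG channels (left/right
#' outer canthi; left/right superior and inferior) and to EEG contamination
#' through a fixed frontally weighted mixing. Sign conventions: a rightward
#' saccade makes the horizontal EOG derivative (right minus left outer
#' canthus) positive; upward gaze and blinks make the vertical derivatives
#' (superior minus inferior) positive.
#'
#' @param gaze_h,gaze_v horizontal / vertical gaze traces (arbitrary units,
#'   same length).
#' @param blink_times blink instants, seconds (may be empty).
#' @param fs sampling rate, Hz.
#' @param lf leadfield (for electrode positions; frontal weighting).
#' @param gain global contamination gain; 0 yields zero EEG contamination.
#' @return list with `eog` (6 x n, channel names `EOG-lo/ro/ls/li/rs/ri`),
#'   `contamination` (n_eeg x n, uV) and the three artifact source traces.
#' @export
simulate_eye_artifacts <- function(gaze_h, gaze_v, blink_times, fs, lf,
                                   gain = 1) {
  n <- length(gaze_h)
  stopifnot(length(gaze_v) == n)
  t <- (seq_len(n) - 1) / fs
  bl <- numeric(n)
  for (b in blink_times) bl <- bl + exp(-(t - b)^2 / (2 * 0.05^2))
  src <- rbind(h = gaze_h, v = gaze_v, blink = bl)

  # EOG channel mixing (rows: lo, ro, ls, li, rs, ri); units ~ uV per unit
  # gaze deflection
  M <- matrix(c(
    -50, 5, 0,     # left outer canthus
    50, 5, 0,      # right outer canthus
    -8, 40, 120,   # left superior
    -8, -30, 25,   # left inferior
    8, 40, 120,    # right superior
    8, -30, 25     # right inferior
  ), nrow = 6, byrow = TRUE)
  eog <- M %*% src
  rownames(eog) <- c("EOG-lo", "EOG-ro", "EOG-ls", "EOG-li", "EOG-rs",
                     "EOG-ri")

  # EEG contamination: strongest frontally, horizontal component lateralized
  pos <- lf$channel_positions / lf$radius
  frontality <- exp((pos[, 2] - 1) / 0.4)
  W <- cbind(h = 15 * pos[, 1] * frontality,
             v = 12 * frontality,
             blink = 40 * frontality^1.5)
  contamination <- gain * (W %*% src)
  list(eog = eog, contamination = contamination, sources = src)
}

# 1/f (pink) noise via spectral shaping, unit variance
.pink_noise <- function(n, nrow = 1) {
  m <- matrix(stats::rnorm(nrow * n), nrow, n)
  f <- stats::mvfft(t(m))  # columns are series
  freq <- c(0, seq_len(n - 1))
  freq <- pmin(freq, n - freq)
  scale <- 1 / sqrt(pmax(freq, 1) / n)
  f <- f * scale
  out <- t(Re(stats::mvfft(f, inverse = TRUE))) / n
  sw <- sqrt(rowMeans(out^2))
  out / ifelse(sw > 0, sw, 1)
}

#' Generate a full synthetic experiment
#'
#' Produces the continuous task recording (EEG + EOG at `fs`), the cursor
#' distance recording (at `fs_cursor`), the trial table with ground truth,
#' and a calibration recording (rest in the first half; scripted blinks and
#' saccades in the second half, emulating the dedicated artifact blocks).
#' The EEG equals leadfield-projected sources + spatially correlated pink
#' noise + eye contamination; with `return_components = TRUE` the three
#' channel-space components are exported separately (their sum is the EEG
#' exactly).
#'
#' @param config from [synth_config()].
#' @param seed integer seed; identical (config, seed) give identical output.
#' @param return_components export clean/noise/contamination EEG components.
#' @return object of class `synth_experiment`: list with `eeg`, `cursor`,
#'   `trials`, `calibration`, `leadfield`, `prep`, `config` (and
#'   `components` when requested).
#' @export
generate_experiment <- function(config = synth_config(), seed = 1L,
                                return_components = FALSE) {
  if (config$n_trials < 8) stop("`n_trials` must be >= 8")
  prep <- .synth_prepare(config, seed)
  lf <- prep$leadfield
  trials <- build_trial_table(config$n_trials, config, seed = seed + 2L)

  fs <- config$fs
  n_per_trial <- round(config$trial_period * fs)
  n_samp <- config$n_trials * n_per_trial
  n_eeg <- config$n_channels
  t_rel <- seq(0, config$trial_period - 1 / fs, by = 1 / fs)

  # clean projected activity, built trial-by-trial from channel patterns
  clean <- matrix(0, n_eeg, n_samp)
  for (i in seq_len(config$n_trials)) {
    tr <- trials[i, ]
    onset_rel <- tr$truth_move_onset - tr$t_trial_start
    cond_amp <- if (tr$condition == "exe") 1 else config$obs_scale
    w_mrcp <- .mrcp_wave(t_rel, onset_rel) * cond_amp
    w_vep <- .vep_wave(t_rel, 2.0) + .vep_wave(t_rel, 2.5)
    w_dir <- .dir_wave(t_rel, 2.5)
    block <- prep$patterns$mrcp %o% w_mrcp +
      prep$patterns$vep %o% w_vep +
      prep$patterns$dir[[tr$direction]] %o% w_dir
    cols <- ((i - 1) * n_per_trial + 1):(i * n_per_trial)
    clean[, cols] <- block
  }

  .with_seed(seed + 3L, {
    # spatially correlated pink noise: random deep dipoles x pink series
    # (more sources than channels, so the noise is spatially full rank)
    n_noise <- 80L
    topo <- matrix(0, n_eeg, n_noise)
    for (k in seq_len(n_noise)) {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      pos <- d * stats::runif(1, 0.02, 0.07)
      mom <- stats::rnorm(3); mom <- mom / sqrt(sum(mom^2))
      topo[, k] <- sphere_dipole_potential(lf$channel_positions, pos, mom,
                                           radius = lf$radius,
                                           sigma = lf$sigma)
    }
    topo <- apply(topo, 2, function(x) x / stats::sd(x))
    noise <- topo %*% .pink_noise(n_samp, n_noise) / sqrt(n_noise) *
      config$noise_sd

    # gaze follows the target after the catch-up saccade; returns near trial
    # end; occasional blinks in the preparation period
    tt <- (seq_len(n_samp) - 1) / fs
    gaze_h <- numeric(n_samp)
    gaze_v <- numeric(n_samp)
    blink_times <- numeric()
    for (i in seq_len(config$n_trials)) {
      tr <- trials[i, ]
      sacc <- tr$truth_saccade
      back <- tr$t_trial_start + config$trial_period - 0.8
      prof <- 1 / (1 + exp(-(tt - sacc) / 0.012)) -
        1 / (1 + exp(-(tt - back) / 0.05))
      ang <- .DIR_ANGLE[[tr$direction]]
      gaze_h <- gaze_h + cos(ang) * prof
      gaze_v <- gaze_v + sin(ang) * prof
      if (stats::runif(1) < 0.5) {
        blink_times <- c(blink_times,
                         tr$t_trial_start + stats::runif(1, 0.2, 1.6))
      }
    }
    eye <- simulate_eye_artifacts(gaze_h, gaze_v, blink_times, fs, lf,
                                  gain = config$artifact_gain)
    eog_noise <- matrix(stats::rnorm(6 * n_samp, sd = 0.3), 6, n_samp)

    # cursor distance trace at fs_cursor
    n_cur <- round(config$n_trials * config$trial_period * config$fs_cursor)
    tc <- (seq_len(n_cur) - 1) / config$fs_cursor
    cursor <- numeric(n_cur)
    for (i in seq_len(config$n_trials)) {
      tr <- trials[i, ]
      onset_abs <- tr$truth_move_onset
      back <- tr$t_trial_start + config$trial_period - 0.8
      prof <- minimum_jerk(tc, onset_abs, tr$truth_duration) *
        (1 - 1 / (1 + exp(-(tc - back) / 0.05)))
      cursor <- cursor + prof
    }
    if (config$cursor_noise_sd > 0) {
      jit <- stats::rnorm(n_cur, sd = config$cursor_noise_sd)
      jit <- as.numeric(stats::filter(jit, rep(1 / 9, 9), sides = 2,
                                      circular = TRUE))
      cursor <- cursor + jit * (1 - pmin(cursor, 1))
    }

    # calibration: rest, then scripted blinks (every 2 s) and saccades
    n_cal <- round(config$calib_duration * fs)
    tcal <- (seq_len(n_cal) - 1) / fs
    half <- config$calib_duration / 2
    cal_blinks <- seq(half + 1, config$calib_duration - 1, by = 2)
    sacc_times <- seq(half + 1.5, config$calib_duration - 2, by = 2.5)
    gh <- numeric(n_cal); gv <- numeric(n_cal)
    for (k in seq_along(sacc_times)) {
      s <- sacc_times[k]
      sgn <- if (k %% 2 == 0) 1 else -1
      pr <- 1 / (1 + exp(-(tcal - s) / 0.012)) -
        1 / (1 + exp(-(tcal - s - 1.2) / 0.012))
      # scripted calibration saccades are larger than task saccades,
      # concentrating artifact energy for the regression fit
      if (k %% 4 < 2) gh <- gh + 1.5 * sgn * pr else gv <- gv + 1.5 * sgn * pr
    }
    cal_eye <- simulate_eye_artifacts(gh, gv, cal_blinks, fs, lf,
                                      gain = config$artifact_gain)
    cal_noise <- topo %*% .pink_noise(n_cal, n_noise) / sqrt(n_noise) *
      config$noise_sd
    cal_eog_noise <- matrix(stats::rnorm(6 * n_cal, sd = 0.3), 6, n_cal)
  })

  eeg_data <- clean + noise + eye$contamination
  all_data <- rbind(eeg_data, eye$eog + eog_noise)
  ch_names <- c(lf$channel_names, rownames(eye$eog))
  ch_types <- c(rep("eeg", n_eeg), rep("eog", 6))

  ev <- data.frame(
    label = c(rep("trial_start", config$n_trials),
              rep("cue_condition", config$n_trials),
              rep("cue_direction", config$n_trials)),
    time = c(trials$t_trial_start, trials$t_condition_cue,
             trials$t_direction_cue))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL

  eeg <- new_recording(all_data, fs, ch_names, ch_types, ev)
  cursor_rec <- new_recording(matrix(cursor, 1), config$fs_cursor,
                              "cursor_distance", "cursor")
  calibration <- new_recording(
    rbind(cal_noise + cal_eye$contamination, cal_eye$eog + cal_eog_noise),
    fs, ch_names, ch_types,
    data.frame(label = c("rest_start", "artifact_start"),
               time = c(0, config$calib_duration / 2)))

  out <- list(eeg = eeg, cursor = cursor_rec, trials = trials,
              calibration = calibration, leadfield = lf, prep = prep,
              config = config)
  if (return_components) {
    out$components <- list(clean = clean, noise = noise,
                           contamination = eye$contamination)
  }
  class(out) <- "synth_experiment"
  out
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf("<synth_experiment> %d trials (%d exe / %d obs), %d+%d ch @ %g Hz\n",
              nrow(x$trials), sum(x$trials$condition == "exe"),
              sum(x$trials$condition == "obs"),
              sum(x$eeg$channel_types == "eeg"),
              sum(x$eeg$channel_types == "eog"), x$eeg$fs))
  invisible(x)
}
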