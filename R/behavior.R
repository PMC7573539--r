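#' @title Behavioral event detection and statistics
#' @description
#' Cursor movement onset/offset detection (threshold + tangent refinement),
#' robust outlier flagging, direction-specific eye-movement onsets from EOG
#' derivatives, and the two-way repeated-measures ANOVA over condition and
#' direction.
#' @name behavior
NULL

#' Onset-detection parameters
#'
#' @param threshold initial onset threshold on the baseline-corrected
#'   normalized distance.
#' @param baseline_window length of the baseline window (last part of the
#'   preparation period), s.
#' @param t_prep_end end of the preparation period within the trial, s
#'   (the direction cue).
#' @param refine_window length of the refinement window preceding the
#'   initial estimate, s.
#' @param smooth_taps triangular smoother length in taps (odd), applied
#'   zero-phase at the detection rate.
#' @param offset_threshold distance-to-target threshold defining the
#'   movement offset.
#' @param fs_detect internal detection rate, Hz; traces sampled below this
#'   are polyphase-upsampled first (all analysis streams run at this common
#'   rate).
#' @return parameter list.
#' @export
onset_params <- function(threshold = 0.05, baseline_window = 1,
                         t_prep_end = 2.5, refine_window = 1.75,
                         smooth_taps = 63L, offset_threshold = 0.1,
                         fs_detect = 200) {
  stopifnot(threshold > 0, baseline_window > 0, refine_window > 0,
            smooth_taps %% 2 == 1, offset_threshold > 0)
  as.list(environment())
}

# zero-phase triangular moving average with edge replication
.tri_smooth <- function(x, taps) {
  k <- (taps + 1) / 2 - abs(seq_len(taps) - (taps + 1) / 2)
  k <- k / sum(k)
  half <- (taps - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Detect cursor movement onset and offset
#'
#' Baseline (mean over the last `baseline_window` seconds of the preparation
#' period) is subtracted; the first crossing of `threshold` gives the
#' initial onset estimate; within the preceding `refine_window` seconds of
#' the triangularly smoothed trace the finite-difference derivative
#' (central differences, forward/backward at the edges) is maximized
#' (earliest time-point on ties) and the tangent at that point is
#' intersected with the zero line to give the final onset. The offset is
#' the first time the distance to the target (1 - distance) drops below
#' `offset_threshold`.
#'
#' @param distance normalized cursor-distance trace for one trial
#'   (trial-relative time starting at 0).
#' @param fs sampling rate of `distance`, Hz.
#' @param params from [onset_params()].
#' @return list with `onset`, `offset`, `duration` (s, trial-relative) and
#'   `moved` (FALSE with NA times when the threshold is never crossed).
#' @export
detect_cursor_events <- function(distance, fs, params = onset_params()) {
  if (fs < params$fs_detect) {
    r <- .rat_approx(params$fs_detect / fs)
    distance <- .resample_vec(distance, r$p, r$q)
    fs <- params$fs_detect
  }
  t <- (seq_along(distance) - 1) / fs
  bl_idx <- t >= (params$t_prep_end - params$baseline_window) &
    t < params$t_prep_end
  if (!any(bl_idx)) bl_idx <- seq_len(min(length(t), round(fs)))
  d <- distance - mean(distance[bl_idx])

  i_init <- which(d > params$threshold & t >= params$t_prep_end -
                    params$baseline_window)[1]
  if (is.na(i_init)) {
    return(list(onset = NA_real_, offset = NA_real_, duration = NA_real_,
                moved = FALSE))
  }
  s <- .tri_smooth(d, params$smooth_taps)
  i_lo <- max(1L, i_init - round(params$refine_window * fs))
  idx <- i_lo:i_init
  sv <- s[idx]
  nw <- length(sv)
  der <- if (nw >= 3) {
    c(sv[2] - sv[1], (sv[3:nw] - sv[1:(nw - 2)]) / 2, sv[nw] - sv[nw - 1])
  } else {
    rep(sv[nw] - sv[1], nw)
  }
  j <- which.max(der)  # which.max takes the earliest maximum
  slope <- der[j] * fs
  onset <- if (slope <= 0) t[i_init] else t[idx[j]] - s[idx[j]] / slope

  i_off <- which((1 - d) < params$offset_threshold & t > onset)[1]
  offset <- if (is.na(i_off)) NA_real_ else t[i_off]
  list(onset = onset, offset = offset,
       duration = if (is.na(i_off)) NA_real_ else offset - onset,
       moved = TRUE)
}

#' Robust outlier flagging of trials
#'
#' Flags a trial when the robust z-score (median / 1.4826 MAD) of its
#' movement onset (relative to trial start) or its duration exceeds `k`.
#' When the MAD is zero, every deviating value is flagged (its robust z is
#' infinite).
#'
#' @param onsets trial-relative movement onsets, s.
#' @param durations movement durations, s.
#' @param k robust-SD multiplier.
#' @return logical outlier mask (NA detections are flagged).
#' @export
flag_outlier_trials <- function(onsets, durations, k = 2.5) {
  if (length(onsets) < 3) stop("need at least 3 trials")
  zo <- abs(robust_z(onsets))
  zd <- abs(robust_z(durations))
  miss <- is.na(onsets) | is.na(durations)
  out <- (zo > k) | (zd > k)
  out[is.na(out)] <- TRUE
  out | miss
}

#' Direction-specific eye-movement onsets from EOG derivatives
#'
#' Computes the horizontal derivative (right minus left outer canthus) and
#' vertical derivative (mean of left/right superior-minus-inferior),
#' averages trials of the same direction, and returns the first trial time
#' at which the direction-associated signed derivative exceeds the baseline
#' (1-1.5 s) mean by 3 standard deviations.
#'
#' @param rec broadband `recording` containing the 6 EOG channels (order:
#'   left/right outer canthus, left sup/inf, right sup/inf).
#' @param trials trial table (uses `t_trial_start`, `direction`).
#' @param directions directions to analyze.
#' @param window trial window to scan, s.
#' @param baseline baseline interval within the trial, s.
#' @param z_thresh threshold in baseline SDs.
#' @param min_duration minimum time the derivative must stay above
#'   threshold, s; suppresses single-sample noise crossings in the
#'   trial-averaged trace.
#' @param scan_from earliest trial time considered, s; catch-up saccades
#'   cannot precede the condition cue, and the blink-contaminated
#'   preparation period is excluded.
#' @return named numeric vector of onsets (s, trial-relative); NA when the
#'   threshold is never exceeded.
#' @export
detect_eye_onset <- function(rec, trials, directions = .DIR_LEVELS,
                             window = c(0, 5), baseline = c(1, 1.5),
                             z_thresh = 3, min_duration = 0.025,
                             scan_from = 2.0) {
  eog <- rec$data[rec$channel_types == "eog", , drop = FALSE]
  if (nrow(eog) != 6) stop("expected 6 EOG channels")
  h <- eog[2, ] - eog[1, ]
  v <- ((eog[3, ] - eog[4, ]) + (eog[5, ] - eog[6, ])) / 2
  fs <- rec$fs
  n_win <- round(diff(window) * fs)
  t_rel <- window[1] + (seq_len(n_win) - 1) / fs
  sign_of <- c(right = 1, up = 1, left = -1, down = -1)
  chan_of <- c(right = "h", up = "v", left = "h", down = "v")
  out <- stats::setNames(rep(NA_real_, length(directions)), directions)
  for (d in directions) {
    rows <- trials[trials$direction == d, ]
    if (!nrow(rows)) next
    sig <- if (chan_of[[d]] == "h") h else v
    acc <- numeric(n_win)
    for (i in seq_len(nrow(rows))) {
      i0 <- round((rows$t_trial_start[i] + window[1]) * fs) + 1
      acc <- acc + sig[i0:(i0 + n_win - 1)]
    }
    avg <- sign_of[[d]] * acc / nrow(rows)
    bl <- avg[t_rel >= baseline[1] & t_rel < baseline[2]]
    thr <- mean(bl) + z_thresh * stats::sd(bl)
    k <- max(1L, round(min_duration * fs))
    above <- avg > thr & t_rel >= max(baseline[2], scan_from)
    sustained <- stats::filter(as.numeric(above), rep(1, k), sides = 1) == k
    hit <- which(sustained)[1] - k + 1L
    if (!is.na(hit)) out[d] <- t_rel[hit]
  }
  out
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for condition (2 levels), direction (4 levels) and
#' their interaction, on a complete balanced subject x condition x direction
#' table, with companion post-hoc paired t-tests (Bonferroni-corrected)
#' for each main effect. Uncorrected degrees of freedom are used for the
#' 4-level factor (no sphericity correction).
#'
#' @param values 3-D array subjects x conditions x directions (dimnames
#'   optional) of cell means.
#' @return list with `anova` (data.frame: effect, F, df1, df2, p) and
#'   `posthoc` (data.frame of pairwise paired t-tests with Bonferroni
#'   adjusted p).
#' @export
rm_anova_two_way <- function(values) {
  if (length(dim(values)) != 3) {
    stop("`values` must be a subjects x conditions x directions array")
  }
  if (anyNA(values)) stop("missing cells in the ANOVA table")
  ns <- dim(values)[1]; nc <- dim(values)[2]; nd <- dim(values)[3]
  cond_lv <- dimnames(values)[[2]] %||% paste0("c", seq_len(nc))
  dir_lv <- dimnames(values)[[3]] %||% paste0("d", seq_len(nd))
  df <- expand.grid(subject = factor(seq_len(ns)),
                    condition = factor(cond_lv, levels = cond_lv),
                    direction = factor(dir_lv, levels = dir_lv))
  df$y <- as.numeric(values)
  fit <- stats::aov(y ~ condition * direction +
                      Error(subject / (condition * direction)), data = df)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    i <- which(trimws(rownames(tb)) == term)
    data.frame(effect = term, F = tb[i, "F value"],
               df1 = tb[i, "Df"], df2 = tb[nrow(tb), "Df"],
               p = tb[i, "Pr(>F)"], row.names = NULL)
  }
  an <- rbind(pull("Error: subject:condition", "condition"),
              pull("Error: subject:direction", "direction"),
              pull("Error: subject:condition:direction",
                   "condition:direction"))

  # post-hoc paired t-tests on subject-level marginal means
  ph <- list()
  safe_t <- function(x, y) {
    tryCatch(stats::t.test(x, y, paired = TRUE),
             error = function(e) list(statistic = NA_real_, p.value = NA_real_,
                                      estimate = mean(x - y)))
  }
  marg_dir <- apply(values, c(1, 3), mean)
  prs <- utils::combn(nd, 2)
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    tt <- safe_t(marg_dir[, i], marg_dir[, j])
    ph[[length(ph) + 1]] <- data.frame(
      factor = "direction", level_a = dir_lv[i], level_b = dir_lv[j],
      t = unname(tt$statistic), p = tt$p.value,
      mean_diff = unname(tt$estimate))
  }
  if (nc == 2) {
    marg_c <- apply(values, c(1, 2), mean)
    tt <- safe_t(marg_c[, 1], marg_c[, 2])
    ph[[length(ph) + 1]] <- data.frame(
      factor = "condition", level_a = cond_lv[1], level_b = cond_lv[2],
      t = unname(tt$statistic), p = tt$p.value,
      mean_diff = unname(tt$estimate))
  }
  ph <- do.call(rbind, ph)
  ph$p_bonf <- pmin(1, ph$p * vapply(ph$factor, function(f) {
    sum(ph$factor == f)
  }, 0))
  list(anova = an, posthoc = ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect behavioral events for every trial of an experiment
#'
#' Slices the continuous cursor trace per trial, runs
#' [detect_cursor_events()], writes detected onset/offset/duration
#' (absolute seconds) and the robust outlier flag into the trial table.
#'
#' @param cursor cursor `recording` (single channel).
#' @param trials trial table.
#' @param params from [onset_params()].
#' @param k outlier multiplier.
#' @param trial_window seconds of trace after each trial start to analyze.
#' @return updated trial table.
#' @export
detect_trial_events <- function(cursor, trials, params = onset_params(),
                                k = 2.5, trial_window = 6) {
  fs <- cursor$fs
  x <- cursor$data[1, ]
  n_win <- round(trial_window * fs)
  for (i in seq_len(nrow(trials))) {
    i0 <- round(trials$t_trial_start[i] * fs) + 1
    seg <- x[i0:min(i0 + n_win - 1, length(x))]
    ev <- detect_cursor_events(seg, fs, params)
    trials$detected_onset[i] <- trials$t_trial_start[i] + ev$onset
    trials$detected_offset[i] <- trials$t_trial_start[i] + ev$offset
    trials$duration[i] <- ev$duration
  }
  trials$outlier <- flag_outlier_trials(
    trials$detected_onset - trials$t_trial_start, trials$duration, k = k)
  trials
}

#' Export a trial table as a BIDS-style events file
#'
#' @param trials trial table with detection columns.
#' @param path output path (tab-separated).
#' @return the path, invisibly.
#' @export
write_trial_events <- function(trials, path) {
  ev <- data.frame(
    onset = trials$t_trial_start,
    duration = rep(6, nrow(trials)),
    trial_type = paste(trials$condition, trials$direction, sep = ":"),
    detected_onset = trials$detected_onset,
    detected_offset = trials$detected_offset,
    movement_duration = trials$duration,
    bad_trial = trials$outlier)
  write_events_tsv(ev, path)
}
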