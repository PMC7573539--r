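#' @title Preprocessing chain
#' @description
#' From raw recording to delta-band, artifact-corrected EEG, in fixed stage
#' order: high-pass + notch filtering, spherical-spline interpolation of bad
#' channels, regression-based eye-artifact correction (fitted on calibration
#' data only), common average reference, variance-based transient artifact
#' removal (HEAR), 3 Hz low-pass, and resampling to 10 Hz.
#' @name preprocess
NULL

# zero-phase IIR filtering with steady-state initial conditions and odd
# reflection padding (so constants and edges are handled exactly)
.filtfilt_pad <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  h0 <- sum(b) / sum(a)
  one_pass <- function(z) {
    pre <- 2 * z[1] - z[(padlen + 1):2]
    post <- 2 * z[length(z)] - z[(length(z) - 1):(length(z) - padlen)]
    zp <- c(pre, z, post)
    y <- signal::filter(b, a, zp,
                        init.x = rep(zp[1], length(b) - 1),
                        init.y = rep(zp[1] * h0, length(a) - 1))
    as.numeric(y)[(padlen + 1):(padlen + length(z))]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase Butterworth filtering of a recording
#'
#' Fourth-order (by default) Butterworth filter applied forward and backward
#' (two passes), so the effective magnitude response is the squared
#' single-pass response and the phase shift is zero. The notch kind is a
#' band-stop centered on `cutoff` (width `notch_width`).
#'
#' @param rec a `recording`.
#' @param kind `"highpass"`, `"lowpass"` or `"notch"`.
#' @param cutoff cutoff (or notch center) frequency, Hz; must be below
#'   Nyquist.
#' @param order filter order (per pass).
#' @param zero_phase apply forward-backward (default); otherwise one causal
#'   pass.
#' @param notch_width full stop-band width for `kind = "notch"`, Hz.
#' @param channels channel types to filter (others pass through untouched).
#' @return filtered `recording`.
#' @export
filter_signal <- function(rec, kind = c("highpass", "lowpass", "notch"),
                          cutoff, order = 4L, zero_phase = TRUE,
                          notch_width = 4, channels = c("eeg", "eog")) {
  kind <- match.arg(kind)
  nyq <- rec$fs / 2
  hi <- if (kind == "notch") cutoff + notch_width / 2 else cutoff
  if (hi >= nyq) stop("cutoff must be below the Nyquist frequency")
  flt <- switch(kind,
    highpass = signal::butter(order, cutoff / nyq, type = "high"),
    lowpass = signal::butter(order, cutoff / nyq, type = "low"),
    notch = signal::butter(max(1L, order %/% 2L),
                           c(cutoff - notch_width / 2, hi) / nyq,
                           type = "stop"))
  padlen <- max(3 * (length(flt$a) - 1),
                min(ceiling(2 * rec$fs / max(cutoff - notch_width / 2 *
                                               (kind == "notch"), 0.1)),
                    ncol(rec$data) - 1))
  rows <- which(rec$channel_types %in% channels)
  out <- rec$data
  for (r in rows) {
    out[r, ] <- if (zero_phase) {
      .filtfilt_pad(flt$b, flt$a, rec$data[r, ], padlen)
    } else {
      as.numeric(signal::filter(flt$b, flt$a, rec$data[r, ]))
    }
  }
  .set_data(rec, out)
}

# ---------------------------------------------------------------------------
# spherical-spline channel interpolation

# Perrin-style spline kernel g(cos(theta)) with stiffness m and nmax terms
.spline_g <- function(cosang, m = 4L, nmax = 50L) {
  leg <- .legendre_table(cosang, nmax)
  n <- seq_len(nmax)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  drop(crossprod(leg$P, w)) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by spherical-spline estimates computed from
#' the remaining good EEG channels (stiffness m = 4). The spline reproduces
#' constants exactly and smooth low-order fields to a few percent. Good
#' channels are untouched.
#'
#' @param rec a `recording`.
#' @param bad_channels channel names or indices (within `rec`).
#' @param channel_positions n_channels x 3 electrode positions (only rows
#'   for EEG channels are used); defaults to positions stored in `attr(rec,
#'   "channel_positions")` if present.
#' @param reg ridge regularization added to the spline system.
#' @return `recording` with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad_channels, channel_positions,
                                 reg = 1e-8) {
  if (length(bad_channels) == 0) return(rec)
  if (is.character(bad_channels)) {
    bad_channels <- match(bad_channels, rec$channel_names)
  }
  if (anyNA(bad_channels) || !all(bad_channels %in% seq_len(nrow(rec$data)))) {
    stop("bad channels must be a subset of the recording's channels")
  }
  eeg_idx <- which(rec$channel_types == "eeg")
  bad <- intersect(bad_channels, eeg_idx)
  good <- setdiff(eeg_idx, bad)
  if (length(good) < 4) stop("need at least 4 good EEG channels")
  pos <- channel_positions
  u <- pos / sqrt(rowSums(pos^2))
  cg <- function(i, j) pmin(1, pmax(-1, tcrossprod(u[i, , drop = FALSE],
                                                   u[j, , drop = FALSE])))
  # map recording channel index -> row of `pos` (EEG channels in order)
  pos_row <- match(seq_len(nrow(rec$data)), eeg_idx)
  Ggg <- matrix(.spline_g(as.numeric(cg(pos_row[good], pos_row[good]))),
                length(good), length(good))
  Gbg <- matrix(.spline_g(as.numeric(cg(pos_row[bad], pos_row[good]))),
                length(bad), length(good))
  ng <- length(good)
  A <- rbind(cbind(Ggg + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  out <- rec$data
  out[bad, ] <- sweep(Gbg %*% w, 2, c0, `+`)
  .set_data(rec, out)
}

# ---------------------------------------------------------------------------
# eye-artifact correction (regression / subspace subtraction)

# EOG-derivative + blink regressors; EOG channels are expected in the order
# left/right outer canthus, left superior/inferior, right superior/inferior
.eog_regressors <- function(eog, blink_loadings = NULL) {
  h <- eog[2, ] - eog[1, ]
  vl <- eog[3, ] - eog[4, ]
  vr <- eog[5, ] - eog[6, ]
  R <- rbind(h = h, vl = vl, vr = vr)
  if (!is.null(blink_loadings)) {
    R <- rbind(R, blink = drop(blink_loadings %*% eog))
  }
  R
}

#' Eye-artifact correction by calibration-fitted regression
#'
#' Fits a linear mapping from an eye-artifact subspace (three EOG-derivative
#' regressors plus the first principal component of calibration blink
#' segments) to every EEG channel, on calibration data only, and subtracts
#' the model from the task EEG. EOG channels are passed through unmodified
#' so behavioral analyses keep the raw derivatives.
#'
#' @param rec task `recording` (EEG + EOG channels).
#' @param calibration calibration `recording` containing scripted blinks and
#'   saccades; must be at least `min_calib` seconds long.
#' @param min_calib minimum calibration duration, s.
#' @param blink_z robust z threshold on the vertical derivative used to
#'   locate blink segments in the calibration data.
#' @return list with `recording` (corrected) and `model` (class `eye_model`:
#'   regression coefficients, blink loadings, per-channel calibration
#'   variance after correction — the reference variance used by
#'   [hear_correct()]).
#' @export
correct_eye_artifacts <- function(rec, calibration, min_calib = 10,
                                  blink_z = 4) {
  if (ncol(calibration$data) / calibration$fs < min_calib) {
    stop("calibration recording shorter than the configured minimum")
  }
  eeg_idx <- which(rec$channel_types == "eeg")
  eog_idx <- which(rec$channel_types == "eog")
  if (length(eog_idx) != 6) stop("expected 6 EOG channels")
  cal_eog <- calibration$data[eog_idx, , drop = FALSE]
  cal_eeg <- calibration$data[eeg_idx, , drop = FALSE]

  # blink subspace: first PC of the EOG channels within blink segments.
  # Blinks are transient spikes on the vertical derivative; a running-median
  # detrend removes sustained saccade plateaus so they are not mistaken for
  # blinks
  vm <- (cal_eog[3, ] - cal_eog[4, ] + cal_eog[5, ] - cal_eog[6, ]) / 2
  k <- round(0.8 * calibration$fs)
  if (k %% 2 == 0) k <- k + 1L
  vm_tr <- vm - stats::runmed(vm, k, endrule = "median")
  zb <- robust_z(vm_tr)
  blink_samp <- which(abs(zb) > blink_z)
  blink_loadings <- if (length(blink_samp) > 50) {
    seg <- cal_eog[, blink_samp, drop = FALSE]
    seg <- seg - rowMeans(seg)
    ev <- eigen(tcrossprod(seg) / ncol(seg), symmetric = TRUE)
    v1 <- ev$vectors[, 1]
    if (sum(v1[c(3, 5)]) < 0) v1 <- -v1  # blinks deflect superior channels up
    matrix(v1, 1)
  } else {
    NULL
  }

  Rcal <- .eog_regressors(cal_eog, blink_loadings)
  Rcal_c <- Rcal - rowMeans(Rcal)
  Xcal_c <- cal_eeg - rowMeans(cal_eeg)
  # scale-aware ridge keeps the system solvable when regressors are
  # (numerically) collinear, e.g. identical left/right vertical derivatives
  G <- tcrossprod(Rcal_c)
  B <- Xcal_c %*% t(Rcal_c) %*% solve(G + diag(1e-8 * mean(diag(G)),
                                               nrow(G)))

  corrected_cal <- cal_eeg - B %*% Rcal_c
  calib_var <- apply(corrected_cal, 1, stats::var)

  Rtask <- .eog_regressors(rec$data[eog_idx, , drop = FALSE], blink_loadings)
  out <- rec$data
  out[eeg_idx, ] <- rec$data[eeg_idx, , drop = FALSE] -
    B %*% (Rtask - rowMeans(Rcal))
  model <- structure(list(coef = B, blink_loadings = blink_loadings,
                          regressor_means = rowMeans(Rcal),
                          calib_var = calib_var), class = "eye_model")
  list(recording = .set_data(rec, out), model = model)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over EEG channels from every EEG
#' channel; after CAR the per-sample EEG mean is zero and reapplication is
#' the identity. Non-EEG channels are untouched.
#'
#' @param rec a `recording` with at least two EEG channels.
#' @return re-referenced `recording`.
#' @export
apply_car <- function(rec) {
  eeg_idx <- which(rec$channel_types == "eeg")
  if (length(eeg_idx) < 2) stop("CAR needs at least 2 EEG channels")
  out <- rec$data
  out[eeg_idx, ] <- sweep(out[eeg_idx, , drop = FALSE], 2,
                          colMeans(out[eeg_idx, , drop = FALSE]))
  .set_data(rec, out)
}

# k-nearest-neighbour electrode adjacency (indices into the EEG channels)
.neighbor_graph <- function(positions, k = 4L) {
  n <- nrow(positions)
  d2 <- as.matrix(stats::dist(positions))^2
  lapply(seq_len(n), function(i) order(d2[i, ])[2:(k + 1)])
}

#' Transient high-variance artifact removal (HEAR)
#'
#' Monitors each EEG channel's short-time variance against its calibration
#' variance. The variance ratio is mapped to an artifact probability with a
#' linear ramp, `p = clip((ratio - 1) / (r_sat - 1), 0, 1)` (with the default
#' saturation `r_sat = 5`, a ratio of 3 gives p = 0.5), and the output is the
#' probability-weighted blend of the channel and the mean of its spatial
#' neighbours. Channels whose ratio never exceeds 1 are returned bit-exact.
#'
#' @param rec a `recording`.
#' @param calib_var per-EEG-channel calibration variance (positive).
#' @param channel_positions EEG electrode positions (rows follow the EEG
#'   channels of `rec`).
#' @param window sliding variance window, s.
#' @param r_sat variance ratio at which the artifact probability saturates
#'   at 1.
#' @param k number of spatial neighbours.
#' @return cleaned `recording`.
#' @export
hear_correct <- function(rec, calib_var, channel_positions,
                         window = 0.25, r_sat = 5, k = 4L) {
  eeg_idx <- which(rec$channel_types == "eeg")
  if (length(calib_var) != length(eeg_idx)) {
    stop("`calib_var` must give one variance per EEG channel")
  }
  if (any(!is.finite(calib_var) | calib_var <= 0)) {
    stop("calibration variances must be positive")
  }
  w <- max(3L, round(window * rec$fs))
  if (w %% 2 == 0) w <- w + 1L
  kern <- rep(1 / w, w)
  half <- (w - 1L) %/% 2L
  X <- rec$data[eeg_idx, , drop = FALSE]
  n <- ncol(X)
  nb <- .neighbor_graph(channel_positions, k = min(k, length(eeg_idx) - 1L))
  run_mean <- function(x) {
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    as.numeric(stats::filter(xp, kern, sides = 2))[(half + 1):(half + n)]
  }
  P <- matrix(0, nrow(X), n)
  for (i in seq_len(nrow(X))) {
    mu <- run_mean(X[i, ])
    v <- pmax(run_mean(X[i, ]^2) - mu^2, 0)
    ratio <- v / calib_var[i]
    P[i, ] <- pmin(1, pmax(0, (ratio - 1) / (r_sat - 1)))
  }
  out <- rec$data
  for (i in seq_len(nrow(X))) {
    p <- P[i, ]
    if (all(p == 0)) next
    nb_mean <- colMeans(X[nb[[i]], , drop = FALSE])
    out[eeg_idx[i], ] <- (1 - p) * X[i, ] + p * nb_mean
  }
  .set_data(rec, out)
}

# split a rate factor into stages small enough for well-conditioned filters
.rate_stages <- function(q) {
  out <- integer()
  while (q > 1) {
    f <- max(Filter(function(d) q %% d == 0, 2:min(q, 7)), 1)
    if (f == 1) {
      f <- q  # prime factor > 7: accept a single larger stage
    }
    out <- c(out, f)
    q <- q %/% f
  }
  out
}

# rate conversion by an integer factor pair p/q: zero-stuff upsampling by p
# (zero-phase Butterworth interpolation with exact DC gain), then staged
# anti-alias filtering and decimation
.resample_vec <- function(x, p, q) {
  # 4th-order filters per pass: the zero-phase double pass yields an
  # 8th-order magnitude rolloff while staying numerically well conditioned
  for (f in .rate_stages(p)) {
    n <- length(x)
    up <- numeric(n * f)
    up[seq(1, n * f, by = f)] <- x * f
    bf <- signal::butter(4, 0.85 / f, type = "low")
    x <- .filtfilt_pad(bf$b, bf$a, up, padlen = 20L * f)
  }
  for (f in .rate_stages(q)) {
    bf <- signal::butter(4, 0.85 / f, type = "low")
    x <- .filtfilt_pad(bf$b, bf$a, x, padlen = 20L * f)
    x <- x[seq(1, length(x), by = f)]
  }
  x
}

#' Anti-aliased resampling
#'
#' Rational-rate resampling (zero-stuff interpolation and/or anti-aliased
#' decimation, both with zero-phase Butterworth filters whose DC gain is
#' exactly one, so constants pass through unchanged). Event times are
#' stored in seconds and therefore unchanged.
#'
#' @param rec a `recording`.
#' @param fs_new target rate, Hz (must be below the current rate; the
#'   signal is expected to be low-passed below `fs_new / 2` already, as in
#'   the pipeline order).
#' @return resampled `recording`.
#' @export
resample_signal <- function(rec, fs_new) {
  if (fs_new >= rec$fs) stop("`fs_new` must be below the current rate")
  r <- .rat_approx(fs_new / rec$fs)
  out <- t(apply(rec$data, 1, .resample_vec, p = r$p, q = r$q))
  new_recording(out, fs_new, rec$channel_names, rec$channel_types,
                rec$events)
}

.rat_approx <- function(x, tol = 1e-9) {
  for (q in 1:10000) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < tol) return(list(p = p, q = q))
  }
  stop("cannot express the resampling ratio as a small rational")
}

#' Run the full preprocessing chain
#'
#' Applies the stages in their fixed order: 0.4 Hz high-pass + 50 Hz notch,
#' spherical interpolation of bad channels, eye-artifact correction (fitted
#' on the calibration recording), common average reference, HEAR, 3 Hz
#' low-pass and resampling to 10 Hz. Returns both the delta-band 10 Hz
#' recording and the broadband (high-passed, cleaned) recording that epoch
#' rejection operates on, plus the eye model. The executed stage order is
#' recorded and asserted.
#'
#' @param rec raw task `recording` (EEG + EOG).
#' @param calibration calibration `recording`.
#' @param channel_positions EEG electrode positions.
#' @param bad_channels channels to interpolate (may be empty).
#' @param hp,lp,notch,fs_out chain parameters (Hz).
#' @param hear_args list of extra arguments to [hear_correct()].
#' @return list with `delta` (10 Hz delta-band recording), `broadband`
#'   (cleaned broadband recording at the original rate), `eye_model`,
#'   `calibration_delta` (calibration put through the same chain, for the
#'   noise-covariance estimate) and `stages` (ordered stage log).
#' @export
preprocess_recording <- function(rec, calibration, channel_positions,
                                 bad_channels = integer(),
                                 hp = 0.4, lp = 3.0, notch = 50,
                                 fs_out = 10, hear_args = list()) {
  stages <- character()
  push <- function(s) stages <<- c(stages, s)

  step_hp <- function(x) {
    x <- filter_signal(x, "highpass", hp)
    if (!is.null(notch) && notch + 2 < x$fs / 2) {
      x <- filter_signal(x, "notch", notch)
    }
    x
  }
  rec <- step_hp(rec); push("highpass_notch")
  calibration <- step_hp(calibration)
  rec <- interpolate_channels(rec, bad_channels, channel_positions)
  calibration <- interpolate_channels(calibration, bad_channels,
                                      channel_positions)
  push("interpolate")
  ec <- correct_eye_artifacts(rec, calibration)
  rec <- ec$recording; push("eye_correction")
  cal_corr <- correct_eye_artifacts(calibration, calibration)$recording
  rec <- apply_car(rec); push("car")
  cal_corr <- apply_car(cal_corr)
  eeg_idx <- which(cal_corr$channel_types == "eeg")
  calib_var <- apply(cal_corr$data[eeg_idx, , drop = FALSE], 1, stats::var)
  rec <- do.call(hear_correct,
                 c(list(rec, calib_var, channel_positions), hear_args))
  push("hear")
  broadband <- rec
  rec <- filter_signal(rec, "lowpass", lp); push("lowpass")
  cal_delta <- filter_signal(cal_corr, "lowpass", lp)
  rec <- resample_signal(rec, fs_out); push("resample")
  cal_delta <- resample_signal(cal_delta, fs_out)

  stopifnot(identical(stages, c("highpass_notch", "interpolate",
                                "eye_correction", "car", "hear",
                                "lowpass", "resample")))
  list(delta = rec, broadband = broadband, eye_model = ec$model,
       calibration_delta = cal_delta, stages = stages)
}
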