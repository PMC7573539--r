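#' Trials x channels x time epoch container
#'
#' @param data 3-D array trials x channels x time.
#' @param time time vector, s, relative to the alignment anchor.
#' @param fs sampling rate, Hz.
#' @param alignment `"trial_start"` or `"movement_onset"`.
#' @param band `"broadband"` or `"delta"`.
#' @param channel_names channel names.
#' @param rejected logical rejection mask, one per trial.
#' @return object of class `epochs`.
#' @export
new_epochs <- function(data, time, fs, alignment, band,
                       channel_names = NULL,
                       rejected = rep(FALSE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3, length(time) == dim(data)[3],
            length(rejected) == dim(data)[1])
  if (length(time) > 1) {
    dt <- diff(time)
    stopifnot(all(dt > 0), diff(range(dt)) < 1e-9)
  }
  structure(list(data = data, time = time, fs = fs, alignment = alignment,
                 band = band, channel_names = channel_names,
                 rejected = rejected),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf(
    "<epochs> %d trials x %d channels x %d samples (%s, %s), %d rejected\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$alignment, x$band,
    sum(x$rejected)))
  invisible(x)
}

#' Extract epochs from a continuous recording
#'
#' Cuts one epoch per anchor using the half-open sample convention
#' `[a, b)`: an epoch holds `floor((b - a) * fs)` samples starting at the
#' first sample at or after `anchor + a`. At 10 Hz, the trial-aligned
#' window [0.75, 4.75) gives 40 samples and the movement-aligned window
#' [-2, 1.25) gives 32.
#'
#' @param rec a `recording` (only EEG channels are epoched).
#' @param anchors anchor times, s (absolute within the recording).
#' @param window c(a, b) epoch window, s, relative to the anchor.
#' @param alignment alignment tag stored in the result.
#' @param band band tag stored in the result.
#' @return an `epochs` object.
#' @export
extract_epochs <- function(rec, anchors, window,
                           alignment = "trial_start", band = "broadband") {
  fs <- rec$fs
  n_t <- floor(diff(window) * fs + 1e-9)
  eeg_idx <- which(rec$channel_types == "eeg")
  n_samp <- ncol(rec$data)
  out <- array(NA_real_, c(length(anchors), length(eeg_idx), n_t))
  for (i in seq_along(anchors)) {
    s0 <- round((anchors[i] + window[1]) * fs) + 1
    if (s0 < 1 || s0 + n_t - 1 > n_samp) {
      stop(sprintf("epoch %d ([%g, %g] s around %g s) exceeds the recording",
                   i, window[1], window[2], anchors[i]))
    }
    out[i, , ] <- rec$data[eeg_idx, s0:(s0 + n_t - 1)]
  }
  new_epochs(out, time = window[1] + (seq_len(n_t) - 1) / fs, fs = fs,
             alignment = alignment, band = band,
             channel_names = rec$channel_names[eeg_idx])
}

# per-epoch, per-channel statistics used by the z-criteria
.epoch_stats <- function(data, keep) {
  nt <- dim(data)[1]; nc <- dim(data)[2]
  jp <- matrix(NA_real_, nt, nc)
  ku <- matrix(NA_real_, nt, nc)
  va <- matrix(NA_real_, nt, nc)
  for (c in seq_len(nc)) {
    pool <- as.numeric(data[keep, c, ])
    mu <- mean(pool); sd <- stats::sd(pool)
    if (sd == 0) sd <- .Machine$double.eps
    for (i in seq_len(nt)) {
      x <- data[i, c, ]
      # negative mean Gaussian log-density: large for improbable epochs
      jp[i, c] <- -mean(stats::dnorm(x, mu, sd, log = TRUE))
      ku[i, c] <- e1071::kurtosis(x, type = 1)
      va[i, c] <- stats::var(x)
    }
  }
  list(jp = jp, ku = ku, va = va)
}

# flag epochs whose per-channel statistic deviates more than `x` robust SDs
# across the surviving trials (max over channels)
.z_flags <- function(stat, keep, x) {
  flags <- rep(FALSE, nrow(stat))
  for (c in seq_len(ncol(stat))) {
    z <- rep(NA_real_, nrow(stat))
    ref <- stat[keep, c]
    ctr <- stats::median(ref)
    sc <- robust_scale_constant(NULL) * stats::median(abs(ref - ctr))
    if (sc == 0) sc <- .Machine$double.eps
    z[keep] <- abs(stat[keep, c] - ctr) / sc
    flags <- flags | (!is.na(z) & z > x)
  }
  flags
}

#' Two-pass statistical epoch rejection
#'
#' Operates on broadband epochs. Criterion 1 flags any epoch containing a
#' sample beyond `amp_thresh` microvolts. Criteria 2-4 flag epochs whose
#' per-channel joint probability (negative mean Gaussian log-density under
#' that channel's all-trial distribution), kurtosis or variance deviates
#' from the across-trial center by more than 6 / 6 / 5 robust SDs (max over
#' channels). The z-criteria run twice: statistics are recomputed on the
#' survivors of the first pass so subtle outliers unmasked by gross ones
#' are caught. The final mask is the union of all criteria and is meant to
#' be applied to the delta-band epochs downstream.
#'
#' @param ep broadband `epochs`.
#' @param amp_thresh amplitude criterion, microvolts.
#' @param z_prob,z_kurt,z_var robust-SD thresholds.
#' @param min_surviving error if fewer epochs survive.
#' @return list with `mask` (logical, TRUE = rejected) and the
#'   per-criterion masks `amplitude`, `pass1`, `pass2`.
#' @export
reject_artifact_epochs <- function(ep, amp_thresh = 200,
                                   z_prob = 6, z_kurt = 6, z_var = 5,
                                   min_surviving = 5L) {
  if (!identical(ep$band, "broadband")) {
    stop("epoch rejection operates on broadband epochs")
  }
  nt <- dim(ep$data)[1]
  amp <- apply(abs(ep$data), 1, max) > amp_thresh

  run_pass <- function(keep) {
    st <- .epoch_stats(ep$data, keep)
    .z_flags(st$jp, keep, z_prob) |
      .z_flags(st$ku, keep, z_kurt) |
      .z_flags(st$va, keep, z_var)
  }
  keep1 <- !amp
  pass1 <- run_pass(keep1)
  keep2 <- keep1 & !pass1
  pass2 <- run_pass(keep2)
  mask <- amp | pass1 | pass2
  if (sum(!mask) < min_surviving) {
    stop("fewer than ", min_surviving, " epochs survive artifact rejection")
  }
  list(mask = mask, amplitude = amp, pass1 = pass1, pass2 = pass2)
}

#' Apply a rejection mask to (delta-band) epochs
#'
#' @param ep an `epochs` object.
#' @param mask logical mask from [reject_artifact_epochs()].
#' @return `epochs` with the mask recorded.
#' @export
apply_rejection <- function(ep, mask) {
  stopifnot(length(mask) == dim(ep$data)[1])
  ep$rejected <- ep$rejected | mask
  ep
}

#' Drop rejected trials
#'
#' @param ep an `epochs` object.
#' @param extra additional logical mask of trials to drop.
#' @return list with `epochs` (survivors only) and `index` (original trial
#'   indices kept).
#' @export
drop_rejected <- function(ep, extra = NULL) {
  drop_mask <- ep$rejected
  if (!is.null(extra)) drop_mask <- drop_mask | extra
  keep <- which(!drop_mask)
  out <- new_epochs(ep$data[keep, , , drop = FALSE], ep$time, ep$fs,
                    ep$alignment, ep$band, ep$channel_names)
  list(epochs = out, index = keep)
}

#' Export epoch rejection decisions as a BIDS-style events file
#'
#' One row per epoched trial, with a `bad_epoch` flag and the criterion
#' provenance (`amplitude`, `pass1`, `pass2`, comma-separated) alongside the
#' behavioral columns.
#'
#' @param trials trial table rows corresponding to the epochs (in order).
#' @param rejection result of [reject_artifact_epochs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_epoch_events <- function(trials, rejection, path) {
  stopifnot(nrow(trials) == length(rejection$mask))
  crit <- vapply(seq_along(rejection$mask), function(i) {
    hits <- c("amplitude", "pass1", "pass2")[c(rejection$amplitude[i],
                                               rejection$pass1[i],
                                               rejection$pass2[i])]
    if (length(hits)) paste(hits, collapse = ",") else "none"
  }, "")
  ev <- data.frame(
    onset = trials$t_trial_start,
    duration = rep(6, nrow(trials)),
    trial_type = paste(trials$condition, trials$direction, sep = ":"),
    bad_epoch = rejection$mask,
    criterion = crit)
  write_events_tsv(ev, path)
}
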