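#' @title Shrinkage-LDA decoding
#' @description
#' Linear discriminant analysis with an analytically shrunk pooled
#' within-class covariance, evaluated per time-point with
#' leave-one-trial-out cross-validation; significance levels are estimated
#' by label shuffling (95th percentile of shuffle accuracies).
#' @name decoding
NULL

#' Fit a shrinkage-LDA classifier
#'
#' Pooled within-class covariance estimated with analytic shrinkage toward
#' a scaled identity (see [shrinkage_covariance()]); one linear discriminant
#' score per class (shared covariance), decisions by maximum score. With
#' shrinkage forced to 1 and equal priors this reduces to nearest class
#' mean in the Euclidean metric.
#'
#' @param features trials x d numeric matrix.
#' @param labels class labels (>= 2 classes, >= 2 trials per class).
#' @param gamma optional fixed shrinkage intensity.
#' @return object of class `slda`: class `means`, shrunk `cov`, score
#'   weights `W` (d x K) and offsets `b`, `classes`, `gamma`.
#' @export
fit_slda <- function(features, labels, gamma = NULL) {
  features <- rbind(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("every class needs at least 2 trials")
  d <- ncol(features)
  M <- matrix(0, length(classes), d)
  Xc <- features
  for (k in seq_along(classes)) {
    idx <- labels == classes[k]
    M[k, ] <- colMeans(features[idx, , drop = FALSE])
    Xc[idx, ] <- sweep(features[idx, , drop = FALSE], 2, M[k, ])
  }
  C <- shrinkage_covariance(Xc, center = FALSE, gamma = gamma)
  W <- solve(C, t(M))                     # d x K
  b <- -0.5 * colSums(t(M) * W) + log(as.numeric(counts) / length(labels))
  structure(list(means = M, cov = C, W = W, b = b, classes = classes,
                 gamma = attr(C, "gamma")), class = "slda")
}

#' Predict class labels with a fitted sLDA model
#'
#' @param object an `slda` model.
#' @param features trials x d matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.slda <- function(object, features, ...) {
  scores <- rbind(features) %*% object$W
  scores <- sweep(scores, 2, object$b, `+`)
  object$classes[max.col(scores, ties.method = "first")]
}

# leave-one-trial-out predictions for one feature matrix
.loto_predict <- function(features, labels, gamma = NULL) {
  n <- nrow(features)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_slda(features[-i, , drop = FALSE], labels[-i], gamma = gamma)
    pred[i] <- predict(fit, features[i, , drop = FALSE])
  }
  pred
}

# feature matrix at time index i (single or windowed trailing history)
.features_at <- function(ep, i, mode, window_len) {
  if (mode == "single") {
    ep$data[, , i, drop = TRUE]
  } else {
    idx <- (i - window_len + 1):i
    matrix(ep$data[, , idx], nrow = dim(ep$data)[1])
  }
}

#' Cross-validated accuracy curve
#'
#' For every time-point, fits and evaluates an sLDA classifier in a
#' leave-one-trial-out scheme (N folds, each trial tested exactly once).
#' Feature vectors are the channel activities at the current time-point
#' (`mode = "single"`) or at the current and `window_len - 1` preceding
#' time-points (`mode = "windowed"`; 64 channels x 6 time-points = 384
#' features at the study defaults).
#'
#' @param ep delta-band `epochs` (surviving trials).
#' @param labels one label per trial.
#' @param mode `"single"` or `"windowed"`.
#' @param window_len trailing window length in time-points (windowed mode).
#' @param gamma optional fixed shrinkage intensity.
#' @param interval optional c(lo, hi) in epoch time: only time-points inside
#'   are evaluated (others stay NA).
#' @param equalize subsample every class to the minimum class count
#'   (seeded) before cross-validation; off by default.
#' @param equalize_seed seed for the equalization subsample.
#' @return object of class `accuracy_curve`: `accuracy` (per time-point),
#'   `time`, `predictions` (trials x time), `labels`, `mode`, `alignment`.
#' @export
crossval_accuracy_curve <- function(ep, labels, mode = c("single", "windowed"),
                                    window_len = 6L, gamma = NULL,
                                    interval = NULL, equalize = FALSE,
                                    equalize_seed = 1L) {
  mode <- match.arg(mode)
  if (equalize) {
    cls <- unique(labels)
    m <- min(table(labels))
    keep <- .with_seed(equalize_seed, {
      sort(unlist(lapply(cls, function(cl) {
        w <- which(labels == cl)
        if (length(w) > m) sort(sample(w, m)) else w
      })))
    })
    ep <- new_epochs(ep$data[keep, , , drop = FALSE], ep$time, ep$fs,
                     ep$alignment, ep$band, ep$channel_names)
    labels <- labels[keep]
  }
  n <- dim(ep$data)[1]
  if (n < 10) stop("need at least 10 trials for cross-validation")
  if (length(labels) != n) stop("one label per trial required")
  nt <- dim(ep$data)[3]
  t_start <- if (mode == "windowed") window_len else 1L
  eval_idx <- t_start:nt
  if (!is.null(interval)) {
    eval_idx <- eval_idx[ep$time[eval_idx] >= interval[1] &
                           ep$time[eval_idx] <= interval[2]]
  }
  acc <- rep(NA_real_, nt)
  preds <- matrix(NA_character_, n, nt)
  for (i in eval_idx) {
    f <- .features_at(ep, i, mode, window_len)
    p <- .loto_predict(f, labels, gamma = gamma)
    preds[, i] <- p
    acc[i] <- mean(p == labels)
  }
  structure(list(accuracy = acc, time = ep$time, predictions = preds,
                 labels = labels, mode = mode, alignment = ep$alignment),
            class = "accuracy_curve")
}

#' Label-shuffling significance level
#'
#' Randomly permutes the class labels across trials, reruns the full
#' leave-one-trial-out cross-validation, and returns the given percentile
#' of the shuffle accuracies as the subject-specific significance level.
#'
#' @param ep delta-band `epochs`.
#' @param labels true labels.
#' @param n_shuffles number of label permutations (>= 100; the study
#'   setting is 1000).
#' @param percentile percentile of the shuffle accuracies (95 by default).
#' @param mode,window_len,gamma passed to the classifier.
#' @param time_subset indices of time-points to evaluate (all when NULL);
#'   accuracies are pooled over shuffles and evaluated time-points.
#' @param seed RNG seed.
#' @return list: `threshold`, `shuffle_accuracies` (vector), `percentile`.
#' @export
shuffle_significance_level <- function(ep, labels, n_shuffles = 1000L,
                                       percentile = 95,
                                       mode = "single", window_len = 6L,
                                       gamma = NULL, time_subset = NULL,
                                       seed = 1L) {
  if (n_shuffles < 100) stop("`n_shuffles` must be >= 100")
  nt <- dim(ep$data)[3]
  t_start <- if (mode == "windowed") window_len else 1L
  if (is.null(time_subset)) time_subset <- t_start:nt
  accs <- .with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(s) {
      lab <- sample(labels)
      vapply(time_subset, function(i) {
        f <- .features_at(ep, i, mode, window_len)
        mean(.loto_predict(f, lab, gamma = gamma) == lab)
      }, 0)
    }))
  })
  list(threshold = as.numeric(stats::quantile(accs, percentile / 100)),
       shuffle_accuracies = accs, percentile = percentile)
}

#' Peak summaries and alignment comparison of accuracy curves
#'
#' For each subject and alignment, finds the peak cross-validated accuracy
#' (and its time) within the test interval, builds the confusion matrix at
#' the peak (rows = true, columns = predicted, counts), and runs a paired
#' permutation t-test on the per-subject peak differences between the two
#' alignments.
#'
#' @param curves_a,curves_b lists of `accuracy_curve` objects (one per
#'   subject) for the two alignments.
#' @param interval_a,interval_b c(lo, hi) test intervals in curve time, s
#'   (cue to movement offset in the study).
#' @param sides sidedness of the paired alignment test.
#' @param n_perm permutations for the paired test.
#' @param seed RNG seed.
#' @return list: `peaks` (data.frame subject/alignment/peak/time),
#'   `confusions` (list of confusion matrices at the peak),
#'   `alignment_test` (paired permutation test on peak differences a - b).
#' @export
summarize_peaks <- function(curves_a, curves_b, interval_a, interval_b,
                            sides = "two", n_perm = 10000L, seed = 1L) {
  if (length(curves_a) < 2 || length(curves_a) != length(curves_b)) {
    stop("need matched curves for >= 2 subjects")
  }
  peak_of <- function(cv, interval) {
    ok <- which(cv$time >= interval[1] & cv$time <= interval[2] &
                  !is.na(cv$accuracy))
    if (!length(ok)) stop("empty test interval")
    i <- ok[which.max(cv$accuracy[ok])]
    conf <- table(true = cv$labels,
                  predicted = factor(cv$predictions[, i],
                                     levels = sort(unique(cv$labels))))
    list(peak = cv$accuracy[i], time = cv$time[i], confusion = conf)
  }
  pa <- lapply(curves_a, peak_of, interval = interval_a)
  pb <- lapply(curves_b, peak_of, interval = interval_b)
  peaks <- data.frame(
    subject = rep(seq_along(curves_a), 2),
    alignment = rep(c(curves_a[[1]]$alignment, curves_b[[1]]$alignment),
                    each = length(curves_a)),
    peak = c(vapply(pa, `[[`, 0, "peak"), vapply(pb, `[[`, 0, "peak")),
    peak_time = c(vapply(pa, `[[`, 0, "time"), vapply(pb, `[[`, 0, "time")))
  test <- permutation_paired_ttest(vapply(pa, `[[`, 0, "peak"),
                                   vapply(pb, `[[`, 0, "peak"),
                                   sides = sides, n_perm = n_perm,
                                   seed = seed)
  list(peaks = peaks,
       confusions = list(a = lapply(pa, `[[`, "confusion"),
                         b = lapply(pb, `[[`, "confusion")),
       alignment_test = test)
}
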