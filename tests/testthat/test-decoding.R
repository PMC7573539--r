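mk_epochs <- function(dat, fs = 10, alignment = "trial_start") {
  new_epochs(dat, time = seq_len(dim(dat)[3]) / fs, fs = fs,
             alignment = alignment, band = "delta")
}

test_that("sLDA approaches the Bayes rate for spherical Gaussian classes", {
  set.seed(20)
  d <- 8; delta <- 1.5
  mu <- rep(delta / sqrt(d), d)  # ||mu - (-mu)|| = 2|mu| = Delta... no:
  mu <- rep(delta / (2 * sqrt(d)), d)  # class means +/- mu, separation Delta
  n <- 1500
  X <- rbind(matrix(rnorm(n * d), n) + rep(mu, each = n),
             matrix(rnorm(n * d), n) - rep(mu, each = n))
  y <- rep(c("a", "b"), each = n)
  fit <- fit_slda(X, y)
  nt <- 4000
  Xt <- rbind(matrix(rnorm(nt * d), nt) + rep(mu, each = nt),
              matrix(rnorm(nt * d), nt) - rep(mu, each = nt))
  yt <- rep(c("a", "b"), each = nt)
  acc <- mean(predict(fit, Xt) == yt)
  expect_equal(acc, pnorm(delta / 2), tolerance = 0.02)
})

test_that("full shrinkage reduces sLDA to nearest class mean", {
  set.seed(22)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rep(c("a", "b", "c", "d"), each = 10)
  fit <- fit_slda(X, y, gamma = 1)
  pred <- predict(fit, X)
  M <- fit$means
  nearest <- fit$classes[apply(X, 1, function(x) {
    which.min(colSums((t(M) - x)^2))
  })]
  expect_equal(pred, nearest)
})

test_that("singular feature sets are handled by shrinkage", {
  set.seed(23)
  X <- matrix(rnorm(20 * 3), 20)
  X <- cbind(X, X)  # duplicated dimensions: singular sample covariance
  y <- rep(c("a", "b"), 10)
  fit <- fit_slda(X, y)
  expect_true(all(is.finite(fit$W)))
  expect_gt(attr(fit$cov, "gamma"), 0)
  expect_error(fit_slda(X[1:3, ], c("a", "a", "b")), "2 trials")
})

test_that("leave-one-trial-out curve matches a brute-force enumeration", {
  set.seed(24)
  nt <- 12; nc <- 3; ns <- 4
  dat <- array(rnorm(nt * nc * ns), c(nt, nc, ns))
  dat[1:6, 1, 2] <- dat[1:6, 1, 2] + 2
  labels <- rep(c("x", "y"), each = 6)
  ep <- mk_epochs(dat)
  cv <- crossval_accuracy_curve(ep, labels)
  # brute force: every trial is tested exactly once per time-point
  for (i in seq_len(ns)) {
    preds <- character(nt)
    for (k in seq_len(nt)) {
      fit <- fit_slda(dat[-k, , i], labels[-k])
      preds[k] <- predict(fit, matrix(dat[k, , i], 1))
    }
    expect_equal(cv$predictions[, i], preds)
    expect_equal(cv$accuracy[i], mean(preds == labels))
  }
  expect_error(crossval_accuracy_curve(mk_epochs(dat[1:8, , , drop = FALSE]),
                                       labels[1:8]), "10 trials")
})

test_that("windowed features stack trailing time-points (64 x 6 = 384)", {
  set.seed(25)
  dat <- array(rnorm(12 * 64 * 8), c(12, 64, 8))
  ep <- mk_epochs(dat)
  f <- deltamotor:::.features_at(ep, 6, "windowed", 6L)
  expect_equal(dim(f), c(12, 384))
  # the single-mode vector is the last block of the windowed vector
  expect_equal(f[, 321:384], dat[, , 6])
  cv <- crossval_accuracy_curve(ep, rep(c("a", "b"), 6), mode = "windowed")
  expect_true(all(is.na(cv$accuracy[1:5])))
  expect_false(anyNA(cv$accuracy[6:8]))
})

test_that("separable signals are decoded perfectly; order does not matter", {
  set.seed(26)
  nt <- 16
  dat <- array(rnorm(nt * 5 * 3, sd = 0.01), c(nt, 5, 3))
  labels <- rep(c("a", "b"), each = nt / 2)
  dat[labels == "a", 1, 2] <- dat[labels == "a", 1, 2] + 5
  ep <- mk_epochs(dat)
  cv <- crossval_accuracy_curve(ep, labels)
  expect_equal(cv$accuracy[2], 1)
  perm <- sample(nt)
  cvp <- crossval_accuracy_curve(mk_epochs(dat[perm, , , drop = FALSE]),
                                 labels[perm])
  expect_equal(cvp$accuracy, cv$accuracy)
})

test_that("shuffle significance level is deterministic and ordered", {
  set.seed(27)
  dat <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  ep <- mk_epochs(dat)
  labels <- rep(c("a", "b"), 10)
  s1 <- shuffle_significance_level(ep, labels, n_shuffles = 100, seed = 9)
  s2 <- shuffle_significance_level(ep, labels, n_shuffles = 100, seed = 9)
  expect_identical(s1, s2)
  expect_gte(s1$threshold, median(s1$shuffle_accuracies))
  expect_error(shuffle_significance_level(ep, labels, n_shuffles = 50),
               "100")
})

test_that("increasing signal amplitude never lowers peak accuracy", {
  peaks <- vapply(c(0.3, 1, 3), function(amp) {
    set.seed(41)  # paired seeds: identical noise across amplitudes
    nt <- 40
    noise <- array(rnorm(nt * 6 * 5), c(nt, 6, 5))
    labels <- rep(c("a", "b"), each = nt / 2)
    sig <- array(0, dim(noise))
    sig[labels == "a", 2, 3] <- amp
    cv <- crossval_accuracy_curve(mk_epochs(noise + sig), labels)
    max(cv$accuracy)
  }, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("peak summaries count confusions and compare alignments", {
  set.seed(28)
  mk_curves <- function(shift) {
    lapply(1:3, function(s) {
      nt <- 16
      dat <- array(rnorm(nt * 5 * 6, sd = 0.01), c(nt, 5, 6))
      labels <- rep(c("a", "b"), each = nt / 2)
      dat[labels == "a", 1, 4] <- dat[labels == "a", 1, 4] + shift
      crossval_accuracy_curve(mk_epochs(dat), labels)
    })
  }
  strong <- mk_curves(5)
  weak <- mk_curves(0.02)
  sm <- summarize_peaks(strong, weak, interval_a = c(0.1, 0.6),
                        interval_b = c(0.1, 0.6), n_perm = 500, seed = 1)
  expect_equal(nrow(sm$peaks), 6)
  conf <- sm$confusions$a[[1]]
  # perfect classifier: identity confusion; rows sum to class counts
  expect_equal(as.numeric(diag(conf)), c(8, 8))
  expect_equal(as.numeric(rowSums(conf)), c(8, 8))
  expect_gt(sm$alignment_test$statistic, 0)
  expect_error(summarize_peaks(strong, weak, c(9, 10), c(0.1, 0.6),
                               n_perm = 200), "interval")
})
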