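mk_epoch_rec <- function(nch = 4, dur = 60, fs = 10) {
  set.seed(31)
  new_recording(matrix(rnorm(nch * dur * fs), nch, dur * fs), fs,
                sprintf("C%02d", seq_len(nch)), rep("eeg", nch))
}

test_that("epoch extraction follows the half-open sample convention", {
  rec <- mk_epoch_rec()
  ep <- extract_epochs(rec, anchors = c(5, 15, 25), window = c(0.75, 4.75))
  expect_equal(dim(ep$data)[3], 40)
  epm <- extract_epochs(rec, anchors = c(10, 20), window = c(-2, 1.25),
                        alignment = "movement_onset")
  expect_equal(dim(epm$data)[3], 32)

  # shifting every anchor by one sample shifts contents by one sample
  ep1 <- extract_epochs(rec, anchors = 10, window = c(0, 2))
  ep2 <- extract_epochs(rec, anchors = 10 + 1 / rec$fs, window = c(0, 2))
  expect_equal(ep1$data[1, , -1], ep2$data[1, , -dim(ep2$data)[3]])

  expect_error(extract_epochs(rec, anchors = c(5, 59), window = c(0, 4)),
               "epoch 2")
})

# straight-line reference implementation of the two-pass rejection
oracle_reject <- function(data, zx = c(6, 6, 5)) {
  nt <- dim(data)[1]; nc <- dim(data)[2]
  amp <- apply(abs(data), 1, max) > 200
  stats_of <- function(keep) {
    jp <- ku <- va <- matrix(NA, nt, nc)
    for (c in seq_len(nc)) {
      pool <- as.numeric(data[keep, c, ])
      mu <- mean(pool); sdv <- sd(pool)
      for (i in seq_len(nt)) {
        x <- data[i, c, ]
        jp[i, c] <- -mean(dnorm(x, mu, sdv, log = TRUE))
        m2 <- mean((x - mean(x))^2)
        ku[i, c] <- mean((x - mean(x))^4) / m2^2 - 3
        va[i, c] <- var(x)
      }
    }
    list(jp, ku, va)
  }
  zpass <- function(keep) {
    st <- stats_of(keep)
    fl <- rep(FALSE, nt)
    for (k in 1:3) for (c in seq_len(nc)) {
      ref <- st[[k]][keep, c]
      ctr <- median(ref)
      sc <- stats::mad(ref, constant = 1 / qnorm(0.75))
      if (sc == 0) sc <- .Machine$double.eps
      z <- abs(st[[k]][, c] - ctr) / sc
      fl <- fl | (keep & z > zx[k])
    }
    fl
  }
  p1 <- zpass(!amp)
  p2 <- zpass(!amp & !p1)
  amp | p1 | p2
}

test_that("two-pass rejection matches a brute-force reference", {
  set.seed(12)
  nt <- 24; nc <- 3; ns <- 30
  dat <- array(rnorm(nt * nc * ns, sd = 10), c(nt, nc, ns))
  dat[4, 2, 5] <- 300        # gross outlier (amplitude + stats)
  dat[9, 1, ] <- dat[9, 1, ] * 4    # variance outlier, first pass
  dat[15, 3, ] <- rt(ns, df = 1) * 6  # kurtosis-heavy, possibly subtle
  ep <- new_epochs(dat, time = seq_len(ns) / 10, fs = 10,
                   alignment = "trial_start", band = "broadband")
  got <- reject_artifact_epochs(ep)
  want <- oracle_reject(dat)
  expect_equal(got$mask, want)
  expect_true(got$amplitude[4])
  expect_true(got$mask[9])
  # union property holds trial by trial
  expect_equal(got$mask, got$amplitude | got$pass1 | got$pass2)
})

test_that("rejection catches second-pass-only outliers unmasked by gross ones", {
  set.seed(44)
  nt <- 20; nc <- 2; ns <- 40
  dat <- array(rnorm(nt * nc * ns), c(nt, nc, ns))
  dat[3, 1, ] <- dat[3, 1, ] * 60   # gross variance outlier
  dat[11, 1, ] <- dat[11, 1, ] * 4  # subtle: hidden while the gross one is in
  ep <- new_epochs(dat, seq_len(ns) / 10, 10, "trial_start", "broadband")
  got <- reject_artifact_epochs(ep)
  expect_true(got$mask[3])
  expect_true(got$pass1[3])
  expect_true(got$mask[11])
  expect_equal(got$mask, oracle_reject(dat))
})

test_that("rejection is permutation-equivariant and spread-aware", {
  set.seed(13)
  nt <- 18; dat <- array(rnorm(nt * 2 * 25), c(nt, 2, 25))
  dat[5, 1, ] <- dat[5, 1, ] * 8
  ep <- new_epochs(dat, seq_len(25) / 10, 10, "trial_start", "broadband")
  m1 <- reject_artifact_epochs(ep)$mask
  perm <- sample(nt)
  epp <- new_epochs(dat[perm, , , drop = FALSE], ep$time, 10,
                    "trial_start", "broadband")
  m2 <- reject_artifact_epochs(epp)$mask
  expect_equal(m2, m1[perm])

  # identical epochs: z-criteria reject none
  same <- array(rep(rnorm(2 * 25), each = nt), c(nt, 2, 25))
  eps <- new_epochs(same, seq_len(25) / 10, 10, "trial_start", "broadband")
  expect_false(any(reject_artifact_epochs(eps)$mask))

  expect_error(reject_artifact_epochs(
    new_epochs(dat, seq_len(25) / 10, 10, "trial_start", "delta")),
    "broadband")
})

test_that("injected artifacts are fully detected with few false rejections", {
  set.seed(21)
  nt <- 60; nc <- 6; ns <- 50
  dat <- array(rnorm(nt * nc * ns, sd = 5), c(nt, nc, ns))
  bad <- c(7, 22, 40)
  for (b in bad) dat[b, 2, 10:20] <- dat[b, 2, 10:20] + 5 * 5 * 3
  ep <- new_epochs(dat, seq_len(ns) / 10, 10, "trial_start", "broadband")
  got <- reject_artifact_epochs(ep)
  expect_true(all(got$mask[bad]))                       # 100% sensitivity
  expect_lt(mean(got$mask[-bad]), 0.10)                 # < 10% false alarms
})
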