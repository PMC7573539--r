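balanced_trials <- function(n_per_cell = 1) {
  expand.grid(rep = seq_len(n_per_cell),
              condition = c("exe", "obs"),
              direction = c("right", "up", "left", "down"),
              stringsAsFactors = FALSE)[, c("condition", "direction")]
}

test_that("design matrix coding, z-scoring and orthogonality", {
  tr <- balanced_trials(1)
  d <- build_design_matrix(tr, seed = 1)
  S <- d$S
  expect_equal(dim(S), c(4, 8))
  expect_equal(unname(rowMeans(S[1:3, ])), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(S[1:3, ], 1, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(S["horz", ] * S["vert", ]), 0, tolerance = 1e-12)
  expect_true(all(S["intercept", ] == 1))
  # coding signs survive z-scoring
  expect_gt(S["cond", which(tr$condition == "exe")[1]], 0)
  expect_gt(S["horz", which(tr$direction == "right")[1]], 0)
  expect_lt(S["vert", which(tr$direction == "down")[1]], 0)
})

test_that("cells are subsampled to the minimum count", {
  counts <- c(41, 45, 45, 45, 44, 45, 43, 45)
  cells <- expand.grid(condition = c("exe", "obs"),
                       direction = c("right", "up", "left", "down"),
                       stringsAsFactors = FALSE)
  tr <- cells[rep(seq_len(8), counts), ]
  d <- build_design_matrix(tr, seed = 5)
  expect_equal(ncol(d$S), 41 * 8)
  expect_equal(length(d$index), 328)
  expect_true(!is.unsorted(d$index))

  # permuting a balanced table permutes the design columns identically
  tr8 <- balanced_trials(2)
  d1 <- build_design_matrix(tr8, seed = 1)
  perm <- sample(nrow(tr8))
  d2 <- build_design_matrix(tr8[perm, ], seed = 1)
  expect_equal(d2$S[, order(perm)], d1$S, tolerance = 1e-12)

  expect_error(build_design_matrix(tr[tr$condition == "exe", ]), "cell")
})

# independently coded textbook analytic-shrinkage formula (naive loops)
oracle_shrinkage <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- matrix(0, p, p)
  for (k in seq_len(n)) S <- S + tcrossprod(Xc[k, ]) / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2)
  b2bar <- 0
  for (k in seq_len(n)) {
    b2bar <- b2bar + sum((tcrossprod(Xc[k, ]) - S)^2)
  }
  b2bar <- b2bar / n^2
  gam <- min(b2bar, d2) / d2
  (1 - gam) * S + gam * diag(m, p)
}

test_that("analytic shrinkage matches the textbook formula and its limits", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  got <- shrinkage_covariance(X)
  expect_equal(unclass(got), oracle_shrinkage(X), tolerance = 1e-12,
               ignore_attr = TRUE)

  # consistency: gamma -> 0 for n >> p
  A <- matrix(rnorm(16), 4, 4); Sigma <- crossprod(A) / 4 + diag(4)
  Xl <- matrix(rnorm(1e4 * 4), 1e4, 4) %*% chol(Sigma)
  expect_lt(attr(shrinkage_covariance(Xl), "gamma"), 0.05)

  # extreme undersampling (known zero mean): gamma near 1, output near a
  # scaled identity
  Xs <- matrix(rnorm(20), 2, 10)
  cs <- shrinkage_covariance(Xs, center = FALSE)
  gam <- attr(cs, "gamma")
  expect_gt(gam, 0.5)
  # off-diagonals are pulled toward the scaled-identity target by (1-gamma)
  raw <- crossprod(Xs) / 2
  off <- function(m) max(abs(m - diag(diag(m))))
  expect_lt(off(cs), (1 - gam) * off(raw) + 1e-12)

  expect_error(shrinkage_covariance(matrix(0, 3, 0)), "column")
})

test_that("GLM recovers coefficients exactly in the noiseless limit", {
  tr <- balanced_trials(4)
  des <- build_design_matrix(tr, seed = 1)
  set.seed(3)
  A <- matrix(rnorm(6 * 4), 6, 4)
  X <- A %*% des$S
  fit <- fit_glm(X, des, gamma = 0)
  expect_equal(unname(fit$A), A, tolerance = 1e-10)
  # X = Xhat + E holds exactly for every channel and trial
  expect_equal(fit$Xhat + fit$E, X, tolerance = 1e-12)
  # equivariance: scaling X scales the coefficients
  fit2 <- fit_glm(3 * X, des, gamma = 0)
  expect_equal(unname(fit2$A), 3 * A, tolerance = 1e-9)
})

test_that("intercept coefficients equal the across-trial mean", {
  tr <- balanced_trials(5)
  des <- build_design_matrix(tr, seed = 2)
  set.seed(4)
  X <- matrix(rnorm(8 * ncol(des$S)), 8) + 2
  # exact without shrinkage; within the small shrinkage perturbation with it
  fit0 <- fit_glm(X, des, gamma = 0)
  expect_equal(fit0$A[, "intercept"], rowMeans(X), tolerance = 1e-9)
  fit <- fit_glm(X, des)
  expect_equal(fit$A[, "intercept"], rowMeans(X), tolerance = 0.05)
})

test_that("noisy GLM estimates stay within the analytic standard error", {
  tr <- balanced_trials(50)   # 400 trials
  des <- build_design_matrix(tr, seed = 1)
  set.seed(6)
  A <- matrix(rnorm(10 * 4), 10, 4)
  n <- ncol(des$S)
  X <- A %*% des$S + matrix(rnorm(10 * n), 10, n)
  fit <- fit_glm(X, des)
  # z-scored orthogonal factors: per-coefficient SE = sigma / sqrt(n);
  # compare the Frobenius error with 3x its expected scale
  se <- 1 / sqrt(n)
  expect_lt(sqrt(sum((fit$A - A)^2)), 3 * se * sqrt(10 * 4))
})
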