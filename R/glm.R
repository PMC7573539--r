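#' @title Per-timepoint linear encoding model
#' @description
#' Encodes condition and direction in the preprocessed EEG: for every
#' time-point \eqn{i}, \eqn{X(i) = A(i) S + E(i)} with a 4 x n_trials design
#' \eqn{S} (condition, horizontal and vertical direction factors, intercept)
#' and the least-squares solution \eqn{\hat A(i) = C_{XS}(i) C_{SS}^{-1}},
#' where the 4 x 4 factor covariance \eqn{C_{SS}} is estimated with analytic
#' (Ledoit-Wolf) shrinkage toward a scaled identity.
#' @name encoding_glm
NULL

#' Build the condition/direction design matrix
#'
#' Codes condition as exe = +1 / obs = -1, direction as two orthogonal
#' factors (horizontal: right = +1, left = -1, up/down = 0; vertical:
#' up = +1, down = -1, left/right = 0), equalizes the number of trials per
#' condition x direction cell by seeded subsampling to the minimum cell
#' count, and z-scores the three factor rows. The fourth row is the
#' intercept (all ones).
#'
#' @param trials trial table (surviving trials only); needs `condition`,
#'   `direction`.
#' @param seed subsampling seed.
#' @return list of class `design_matrix`: `S` (4 x n matrix, rows
#'   `cond`, `horz`, `vert`, `intercept`), `index` (positions of the kept
#'   trials within `trials`, in original order), `zscore` (centers and
#'   scales used).
#' @export
build_design_matrix <- function(trials, seed = 1L) {
  cells <- interaction(trials$condition, trials$direction, drop = FALSE)
  full <- as.vector(outer(c("exe", "obs"), .DIR_LEVELS, paste, sep = "."))
  n_cell <- vapply(full, function(cl) sum(cells == cl), 0L)
  if (any(n_cell < 1)) stop("empty condition x direction cell")
  m <- min(n_cell)
  idx <- .with_seed(seed, {
    unlist(lapply(full, function(cl) {
      w <- which(cells == cl)
      if (length(w) > m) sort(sample(w, m)) else w
    }))
  })
  idx <- sort(idx)
  tr <- trials[idx, ]
  cond <- ifelse(tr$condition == "exe", 1, -1)
  horz <- ifelse(tr$direction == "right", 1,
                 ifelse(tr$direction == "left", -1, 0))
  vert <- ifelse(tr$direction == "up", 1,
                 ifelse(tr$direction == "down", -1, 0))
  raw <- rbind(cond = cond, horz = horz, vert = vert)
  ctr <- rowMeans(raw)
  sc <- apply(raw, 1, stats::sd)
  if (any(sc == 0)) stop("a factor is constant after equalization")
  S <- rbind((raw - ctr) / sc, intercept = rep(1, ncol(raw)))
  structure(list(S = S, index = idx, zscore = list(center = ctr, scale = sc)),
            class = "design_matrix")
}

#' Analytic (Ledoit-Wolf) shrinkage covariance
#'
#' Convex combination \eqn{(1-\gamma) S + \gamma m I} of the sample
#' covariance and its scaled-identity target (\eqn{m} = mean diagonal),
#' with the shrinkage intensity computed analytically from the data:
#' \eqn{\gamma = \min(\bar b^2, d^2) / d^2} where \eqn{d^2 = \|S - mI\|_F^2}
#' and \eqn{\bar b^2 = n^{-2} \sum_k \|x_k x_k' - S\|_F^2}. The result is
#' positive definite whenever \eqn{\gamma > 0}.
#'
#' @param samples n x p matrix (rows are observations).
#' @param center subtract column means first (set FALSE when the rows
#'   already include an explicit intercept regressor).
#' @param gamma optional fixed shrinkage intensity overriding the analytic
#'   value (0 disables shrinkage, 1 returns the scaled identity).
#' @return p x p covariance with attributes `gamma` and `target_scale`.
#' @export
shrinkage_covariance <- function(samples, center = TRUE, gamma = NULL) {
  samples <- rbind(samples)
  n <- nrow(samples); p <- ncol(samples)
  if (p == 0) stop("`samples` must have at least one column")
  if (n < 2) stop("need at least 2 observations")
  X <- if (center) sweep(samples, 2, colMeans(samples)) else samples
  S <- crossprod(X) / n
  m <- sum(diag(S)) / p
  if (is.null(gamma)) {
    d2 <- sum((S - diag(m, p))^2)
    if (d2 <= .Machine$double.eps) {
      gamma <- 0
    } else {
      sq_norms <- rowSums(X^2)
      b2bar <- (sum(sq_norms^2) / n - sum(S^2)) / n
      gamma <- min(b2bar, d2) / d2
    }
  }
  gamma <- min(1, max(0, gamma))
  out <- (1 - gamma) * S + gamma * diag(m, p)
  attr(out, "gamma") <- gamma
  attr(out, "target_scale") <- m
  out
}

#' Fit the encoding GLM at one time-point
#'
#' \eqn{\hat A = C_{XS} C_{SS}^{-1}} with the shrunk factor covariance;
#' fitted values \eqn{\hat X = \hat A S} and residuals \eqn{E = X - \hat X}
#' satisfy \eqn{X = \hat X + E} by construction. Moments are uncentered
#' (the intercept is an explicit row of \eqn{S}), so with z-scored factors
#' the intercept coefficients equal the across-trial mean of \eqn{X}.
#'
#' @param X channels x trials activity at one time-point.
#' @param design a `design_matrix` (its trial count must match `ncol(X)`).
#' @param gamma optional fixed shrinkage intensity for \eqn{C_{SS}}.
#' @return list of class `glm_fit`: `A` (channels x 4), `Xhat`, `E`,
#'   `C_XS`, `C_SS`, `gamma`, `resid_stats` (per-channel residual skewness,
#'   excess kurtosis and residual-vs-fitted correlation).
#' @export
fit_glm <- function(X, design, gamma = NULL) {
  X <- rbind(X)
  S <- design$S
  n <- ncol(S)
  if (ncol(X) != n) stop("trial counts of X and the design matrix differ")
  C_XS <- tcrossprod(X, S) / n
  C_SS <- shrinkage_covariance(t(S), center = FALSE, gamma = gamma)
  if (attr(C_SS, "gamma") == 0 && rcond(C_SS) < 1e-12) {
    stop("factor covariance is singular and shrinkage is disabled")
  }
  A <- C_XS %*% solve(C_SS)
  colnames(A) <- rownames(S)
  Xhat <- A %*% S
  E <- X - Xhat
  rs <- t(apply(E, 1, function(e) {
    c(skewness = e1071::skewness(e, type = 1),
      excess_kurtosis = e1071::kurtosis(e, type = 1))
  }))
  rvf <- vapply(seq_len(nrow(X)), function(ch) {
    if (stats::sd(Xhat[ch, ]) == 0 || stats::sd(E[ch, ]) == 0) 0
    else stats::cor(E[ch, ], Xhat[ch, ])
  }, 0)
  structure(list(A = A, Xhat = Xhat, E = E, C_XS = C_XS, C_SS = C_SS,
                 gamma = attr(C_SS, "gamma"),
                 resid_stats = cbind(rs, resid_vs_fitted = rvf)),
            class = "glm_fit")
}

#' Fit the encoding GLM at every time-point of an epochs object
#'
#' @param ep delta-band `epochs` (surviving trials only).
#' @param design `design_matrix` built from the matching trial table; its
#'   `index` selects the epochs used.
#' @param gamma optional fixed shrinkage intensity.
#' @return list of class `glm_timecourse`: `A` (channels x 4 x time array),
#'   `time`, `resid_stats` (channels x 3 x time), `design`.
#' @export
fit_glm_timecourse <- function(ep, design, gamma = NULL) {
  dat <- ep$data[design$index, , , drop = FALSE]
  nt <- dim(dat)[3]
  nc <- dim(dat)[2]
  nf <- nrow(design$S)
  A <- array(NA_real_, c(nc, nf, nt),
             dimnames = list(ep$channel_names, rownames(design$S), NULL))
  rs <- array(NA_real_, c(nc, 3, nt))
  for (i in seq_len(nt)) {
    f <- fit_glm(t(dat[, , i]), design, gamma = gamma)
    A[, , i] <- f$A
    rs[, , i] <- f$resid_stats
  }
  structure(list(A = A, time = ep$time, resid_stats = rs, design = design),
            class = "glm_timecourse")
}
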