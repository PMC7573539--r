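#' @title Group-level permutation statistics and FDR control
#' @description
#' Sign-flip permutation tests for group-average maps, paired permutation
#' t-tests, and Benjamini-Hochberg false-discovery-rate control. Permutation
#' p-values use the +1 smoothing \eqn{p = (1 + \#\{null \ge obs\}) /
#' (1 + n_{perm})}, so p is never zero and never below
#' \eqn{1/(n_{perm}+1)}.
#' @name stats_perm
NULL

#' Sign-flip permutation test on subject effects
#'
#' Builds the null by randomly negating each subject's effect vector before
#' group-averaging and applying `stat_fun` (identity absolute value by
#' default; pass a voxel-norm extractor for orientation-coefficient maps).
#' One-sided: p is the smoothed fraction of permuted statistics at least as
#' large as the observed one, per feature.
#'
#' @param effects subjects x features matrix.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @param stat_fun maps a group-average feature vector to the statistic
#'   vector (default `abs`); e.g. `voxel_norm` for 3-orientation source
#'   coefficients.
#' @param exhaustive enumerate all 2^S sign patterns instead of sampling
#'   (p is then the exact unsmoothed fraction, including the identity
#'   pattern).
#' @return list: `p` (per statistic component), `observed`, `n_perm`.
#' @export
permutation_signflip_test <- function(effects, n_perm = 10000L, seed = 1L,
                                      stat_fun = abs, exhaustive = FALSE) {
  effects <- rbind(effects)
  S <- nrow(effects)
  if (S < 2) stop("need at least 2 subjects")
  obs <- stat_fun(colMeans(effects))
  if (exhaustive) {
    n_perm <- 2^S
    count <- rep(0, length(obs))
    for (code in 0:(n_perm - 1)) {
      signs <- 1 - 2 * as.integer(intToBits(code)[seq_len(S)])
      perm <- stat_fun(colMeans(effects * signs))
      count <- count + (perm >= obs)
    }
    p <- count / n_perm
  } else {
    if (n_perm < 100) stop("`n_perm` must be >= 100")
    count <- rep(0, length(obs))
    .with_seed(seed, {
      for (r in seq_len(n_perm)) {
        signs <- sample(c(-1, 1), S, replace = TRUE)
        perm <- stat_fun(colMeans(effects * signs))
        count <- count + (perm >= obs)
      }
    })
    p <- (1 + count) / (1 + n_perm)
  }
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Paired permutation t-test
#'
#' Sign-flips the paired differences under the null of exchangeable signs
#' and compares the observed t statistic with the permutation distribution.
#' One-sided tests address `a > b`.
#'
#' @param a,b paired samples (equal length >= 2).
#' @param sides `"two"` or `"one"`.
#' @param n_perm number of permutations (ignored when `exhaustive`).
#' @param seed RNG seed.
#' @param exhaustive enumerate all 2^n sign patterns (exact p, identity
#'   included, no smoothing).
#' @return list of class `perm_test`: `statistic` (t), `p`, `n_perm`,
#'   `sides`, `degenerate` (TRUE when all differences are zero, p = 1).
#' @export
permutation_paired_ttest <- function(a, b, sides = c("two", "one"),
                                     n_perm = 10000L, seed = 1L,
                                     exhaustive = FALSE) {
  sides <- match.arg(sides)
  if (length(a) != length(b) || length(a) < 2) {
    stop("`a` and `b` must be paired with length >= 2")
  }
  d <- a - b
  n <- length(d)
  tstat <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(NA_real_)
    mean(x) / (s / sqrt(n))
  }
  t_obs <- tstat(d)
  if (is.na(t_obs)) {
    return(structure(list(statistic = NA_real_, p = 1, n_perm = 0L,
                          sides = sides, degenerate = TRUE),
                     class = "perm_test"))
  }
  cmp <- function(t_perm) {
    t_perm <- t_perm[!is.na(t_perm)]
    if (sides == "two") sum(abs(t_perm) >= abs(t_obs)) else
      sum(t_perm >= t_obs)
  }
  if (exhaustive) {
    n_perm <- 2^n
    tp <- vapply(0:(n_perm - 1), function(code) {
      signs <- 1 - 2 * as.integer(intToBits(code)[seq_len(n)])
      tstat(d * signs)
    }, 0)
    p <- cmp(tp) / n_perm
  } else {
    tp <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        tstat(d * sample(c(-1, 1), n, replace = TRUE))
      }, 0)
    })
    p <- (1 + cmp(tp)) / (1 + n_perm)
  }
  structure(list(statistic = t_obs, p = p, n_perm = n_perm, sides = sides,
                 degenerate = FALSE), class = "perm_test")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure over the supplied p-value family at level `q`.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level.
#' @return list: `mask` (TRUE = rejected), `critical_p` (largest rejected
#'   p, NA when none), `q`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value family")
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  mask <- stats::p.adjust(p, method = "BH") <= q
  list(mask = mask,
       critical_p = if (any(mask)) max(p[mask]) else NA_real_,
       q = q)
}
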