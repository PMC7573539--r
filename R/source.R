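#' @title sLORETA source imaging
#' @description
#' Standardized low-resolution electromagnetic tomography over the
#' synthetic leadfield: a regularized minimum-norm kernel standardized by
#' the diagonal 3 x 3 blocks of its resolution matrix. Source estimates are
#' normalized by a per-subject global-field-power (GFP) constant estimated
#' by repeated random single-sample-per-trial averaging.
#' @name source_imaging
NULL

#' Noise covariance from a rest recording
#'
#' Sample covariance of the (time-centered) channels plus shrinkage by a
#' fraction of the average eigenvalue:
#' \eqn{C + f \cdot \mathrm{mean}(\lambda) I} with
#' \eqn{\mathrm{mean}(\lambda) = \mathrm{tr}(C)/p}.
#'
#' @param rest a `recording` (EEG channels used) or channels x samples
#'   matrix.
#' @param shrink_frac shrinkage fraction of the average eigenvalue
#'   (0.1 by default).
#' @param min_duration minimum rest duration in seconds (recordings only).
#' @return channels x channels covariance.
#' @export
estimate_noise_covariance <- function(rest, shrink_frac = 0.1,
                                      min_duration = 5) {
  if (inherits(rest, "recording")) {
    if (ncol(rest$data) / rest$fs < min_duration) {
      stop("rest recording shorter than the configured minimum")
    }
    X <- rest$data[rest$channel_types == "eeg", , drop = FALSE]
  } else {
    X <- rbind(rest)
  }
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / ncol(Xc)
  if (sum(abs(C)) == 0) stop("rest data has rank 0")
  mean_eig <- sum(diag(C)) / nrow(C)
  C + diag(shrink_frac * mean_eig, nrow(C))
}

#' Compute the sLORETA inverse operator
#'
#' Minimum-norm kernel \eqn{W = L^\top (L L^\top + \lambda^2 C)^{-1}}
#' standardized per voxel by the inverse square root of the corresponding
#' 3 x 3 diagonal block of the resolution matrix \eqn{R = W L}. For
#' noiseless single-dipole data and vanishing regularization the
#' standardized power is maximal at the true voxel (zero localization
#' error).
#'
#' @param lf a `leadfield`.
#' @param noise_cov channels x channels noise covariance (identity when
#'   NULL).
#' @param lambda2 regularization scale applied to the noise covariance.
#' @return list of class `inverse_operator`: `kernel` (standardized,
#'   (3 voxels) x channels), `raw_kernel`, `roi_labels`, `voxel_positions`,
#'   `lambda2`.
#' @export
compute_sloreta_operator <- function(lf, noise_cov = NULL, lambda2 = 0.1) {
  L <- lf$gain
  nch <- nrow(L)
  if (is.null(noise_cov)) noise_cov <- diag(1, nch)
  if (!all(dim(noise_cov) == nch)) {
    stop("noise covariance does not match the leadfield channel count")
  }
  G <- tcrossprod(L) + lambda2 * noise_cov
  W <- t(solve(G, L))            # (3nv) x nch minimum-norm kernel
  R <- W %*% L                   # resolution matrix
  nv <- ncol(L) / 3
  Ws <- W
  for (v in seq_len(nv)) {
    rows <- (3 * v - 2):(3 * v)
    B <- (R[rows, rows] + t(R[rows, rows])) / 2
    e <- eigen(B, symmetric = TRUE)
    lam <- pmax(e$values, max(e$values) * 1e-12)
    Bsqi <- e$vectors %*% diag(1 / sqrt(lam), 3) %*% t(e$vectors)
    Ws[rows, ] <- Bsqi %*% W[rows, , drop = FALSE]
  }
  structure(list(kernel = Ws, raw_kernel = W, roi_labels = lf$roi_labels,
                 voxel_positions = lf$voxel_positions, lambda2 = lambda2),
            class = "inverse_operator")
}

#' Project channel data to source space
#'
#' @param x channels x k matrix (data samples or GLM coefficients).
#' @param inv an `inverse_operator`.
#' @return (3 voxels) x k source estimate (standardized kernel).
#' @export
source_project <- function(x, inv) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  inv$kernel %*% x
}

#' Per-voxel standardized power
#'
#' @param x channels x 1 data vector.
#' @param inv an `inverse_operator`.
#' @return length n_voxels vector of squared-norm standardized estimates.
#' @export
sloreta_power <- function(x, inv) {
  s <- source_project(x, inv)
  voxel_norm(s)^2
}

#' Euclidean norm over the 3 orientations of each voxel
#'
#' @param x (3 voxels) x k matrix (or vector).
#' @return n_voxels x k matrix (or vector) of per-voxel norms.
#' @export
voxel_norm <- function(x) {
  x <- unname(cbind(x))
  if (nrow(x) %% 3 != 0) stop("expected 3 orientation rows per voxel")
  nv <- nrow(x) / 3
  out <- sqrt(x[seq(1, 3 * nv, 3), , drop = FALSE]^2 +
                x[seq(2, 3 * nv, 3), , drop = FALSE]^2 +
                x[seq(3, 3 * nv, 3), , drop = FALSE]^2)
  if (ncol(out) == 1) drop(out) else out
}

#' Combined direction map from horizontal and vertical coefficients
#'
#' Adds the per-voxel orientation norms of the horizontal and vertical
#' direction factors into a single direction-information map.
#'
#' @param horz,vert (3 voxels) x k source coefficients for the two factors.
#' @return n_voxels x k (or vector) direction map.
#' @export
voxel_direction_norm <- function(horz, vert) {
  voxel_norm(horz) + voxel_norm(vert)
}

#' Estimate the global field power normalization constant
#'
#' Repeats `n_reps` times: draw one random time sample from every trial,
#' average the drawn channel vectors, project the average to source space
#' and take the standard deviation across the source components. The GFP
#' estimate is the median over repetitions; it is a single per-subject
#' constant applied to both activity and regression coefficients.
#'
#' @param ep delta-band `epochs`.
#' @param inv an `inverse_operator`.
#' @param n_reps number of repetitions (>= 1; the study setting is 10,000).
#' @param seed RNG seed.
#' @return scalar GFP.
#' @export
estimate_gfp <- function(ep, inv, n_reps = 10000L, seed = 1L) {
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  nt <- dim(ep$data)[1]; nc <- dim(ep$data)[2]; ntime <- dim(ep$data)[3]
  .with_seed(seed, {
    meds <- vapply(seq_len(n_reps), function(r) {
      picks <- sample.int(ntime, nt, replace = TRUE)
      m <- matrix(ep$data[cbind(rep(seq_len(nt), times = nc),
                                rep(seq_len(nc), each = nt),
                                rep(picks, times = nc))], nt, nc)
      stats::sd(drop(inv$kernel %*% colMeans(m)))
    }, 0)
  })
  stats::median(meds)
}

#' Project and GFP-normalize channel-space quantities
#'
#' @param x channels x k matrix (epoch averages or GLM coefficients).
#' @param inv an `inverse_operator`.
#' @param gfp normalization constant from [estimate_gfp()].
#' @return list of class `source_map`: `values` ((3 voxels) x k normalized
#'   source estimate), `gfp`, `roi_labels`.
#' @export
project_and_normalize <- function(x, inv, gfp) {
  .check_positive(gfp, "gfp")
  structure(list(values = source_project(x, inv) / gfp, gfp = gfp,
                 roi_labels = inv$roi_labels), class = "source_map")
}

#' Mean of a voxel map within each ROI
#'
#' @param values n_voxels vector (e.g. a direction-norm map).
#' @param roi_labels per-voxel ROI labels (NA outside ROIs).
#' @return named vector of ROI means (all 8 ROIs, ordered).
#' @export
roi_means <- function(values, roi_labels) {
  rois <- c("PO-left", "PO-right", "SPL-left", "SPL-right",
            "SM1-left", "SM1-right", "PM-left", "PM-right")
  out <- vapply(rois, function(r) {
    idx <- which(roi_labels == r)
    if (!length(idx)) NA_real_ else mean(values[idx])
  }, 0)
  out
}

#' Perturb a leadfield for robustness checks
#'
#' Adds multiplicative Gaussian noise to the gain matrix, emulating a
#' mismatch between the simulation forward model and the imaging forward
#' model (the validation default deliberately reuses the simulation
#' leadfield; this mode quantifies sensitivity to that choice).
#'
#' @param lf a `leadfield`.
#' @param rel_sd relative perturbation SD (fraction of each gain entry's
#'   column RMS).
#' @param seed RNG seed.
#' @return perturbed `leadfield`.
#' @export
perturb_leadfield <- function(lf, rel_sd = 0.05, seed = 1L) {
  .check_positive(rel_sd, "rel_sd")
  g <- lf$gain
  scale <- sqrt(colMeans(g^2))
  .with_seed(seed, {
    g <- g + matrix(stats::rnorm(length(g)), nrow(g)) *
      rep(scale * rel_sd, each = nrow(g))
  })
  lf$gain <- g
  lf
}
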