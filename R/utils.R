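#' Robust scale constant
#'
#' Consistency factor that maps the median absolute deviation (MAD) of a
#' Gaussian sample onto its standard deviation, i.e. \eqn{1/\Phi^{-1}(3/4)}.
#' Rounded to four decimals this is the familiar 1.4826 used throughout the
#' outlier-detection steps of the pipeline.
#'
#' @param digits number of decimals to round to; `NULL` returns the exact
#'   value.
#' @return scalar constant.
#' @export
robust_scale_constant <- function(digits = 4L) {
  k <- 1 / stats::qnorm(0.75)
  if (is.null(digits)) k else round(k, digits)
}

#' Robust z-scores
#'
#' Centers by the median and scales by 1.4826 times the median absolute
#' deviation, so that under Gaussian data the scores behave like classical
#' z-scores but are insensitive to gross outliers.
#'
#' @param x numeric vector.
#' @return numeric vector of robust z-scores. If the MAD is zero, deviating
#'   values map to `Inf` (every deviating point is flagged by any finite
#'   threshold), identical values map to 0.
#' @export
robust_z <- function(x) {
  ctr <- stats::median(x)
  sc <- robust_scale_constant(NULL) * stats::median(abs(x - ctr))
  d <- x - ctr
  if (sc == 0) {
    z <- ifelse(d == 0, 0, Inf)
  } else {
    z <- d / sc
  }
  z
}

# internal: validate a positive scalar
.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

# internal: seeded RNG evaluation that restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
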