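#' Rescale a numeric vector to the unit interval
#'
#' Min-max scaling as used throughout the prioritization stage: each value is
#' mapped to `(v - min) / (max - min)`.  A constant vector maps to all zeros
#' (a documented convention: a criterion with no contrast contributes no
#' priority).  Missing values propagate.
#'
#' @param x numeric vector with at least one finite value.
#' @return numeric vector of the same length with finite values in `[0, 1]`.
#' @examples
#' minmax_scale(c(2, 4, 6))
#' @export
minmax_scale <- function(x) {
  if (length(x) == 0L) stop("minmax_scale: empty input")
  fin <- x[is.finite(x)]
  if (length(fin) == 0L) stop("minmax_scale: no finite values")
  lo <- min(fin)
  hi <- max(fin)
  if (hi == lo) {
    out <- rep(0, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - lo) / (hi - lo)
}

#' Spearman rank correlation of two vectors
#'
#' Thin wrapper over [stats::cor()] with `method = "spearman"` (average ranks
#' for ties).  Returns `NA` when either input is constant, which callers flag
#' rather than error on.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  if (length(unique(x[!is.na(x)])) < 2L || length(unique(y[!is.na(y)])) < 2L) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman", use = "complete.obs")
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# standard error of the mean, NA-safe
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# shared integer-seed splitter: derive a stream-specific seed below 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_positive_int <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("invalid config: %s must be a positive integer", what))
  }
}
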