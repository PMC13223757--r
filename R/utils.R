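# Internal numeric helpers.

# Round half away from zero (ratings are positive, so half-up).
roundHalfUp <- function(x) floor(x + 0.5)

# Deterministic per-subject seed derived from a cohort seed; kept below 2^31.
seedFor <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 1003 + as.numeric(index) * 7919 +
                as.numeric(salt) * 104729) %% 2147483629 + 1)
}

#' Standardize a numeric vector
#'
#' Centers to mean 0 and scales to sample SD 1. The quadratic age regressor
#' used throughout the association models is the square of the standardized
#' value, not the standardized square.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector of z-scores.
#' @examples standardize(c(1, 2, 3))
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stop("standardize() needs at least two values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("standardize() needs nonzero variance")
  (x - mean(x)) / s
}

# Zero-phase IIR filtering with odd-reflection end padding, so that constant
# inputs map to themselves and edge transients do not leak into the series.
zeroPhaseFilter <- function(x, filt) {
  n <- length(x)
  npad <- min(n - 1L, 3L * max(length(filt$b), length(filt$a)) * 10L)
  if (npad < 1L) stop("series too short to filter")
  pre  <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(filt, xp)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[seq(npad + 1L, npad + n)]
}

# Gaussian AIC for an OLS fit, matching stats::AIC on lm objects
# (k coefficients + 1 for the error variance).
gaussianAic <- function(rss, n, k) {
  n * (log(2 * pi * rss / n) + 1) + 2 * (k + 1)
}
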