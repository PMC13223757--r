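#' Demean and detrend a run
#'
#' Removes, per ROI column, the least-squares intercept and linear trend.
#' Applied per run before nuisance regression; idempotent.
#'
#' @param run an [RoiRun-class].
#' @return detrended [RoiRun-class].
#' @export
demeanDetrend <- function(run) {
  stopifnot(is(run, "RoiRun"))
  n <- nFrames(run)
  if (n < 3L) stop("need at least 3 frames to detrend")
  X <- cbind(1, seq_len(n) - (n + 1) / 2)
  beta <- solve(crossprod(X), crossprod(X, run@signal))
  new("RoiRun", signal = run@signal - X %*% beta, tr = run@tr)
}

#' Assemble the nuisance-regressor set
#'
#' Global signal (mean over all ROIs), optional CSF / white-matter
#' channels, and the 24-parameter motion block: the six realignment
#' parameters, their first backward differences (first row 0), and the
#' squares of those 12 (Volterra expansion). All columns are demeaned.
#'
#' @param run an [RoiRun-class] (used for the global signal).
#' @param realignment frames x 6 realignment matrix for the same run.
#' @param csf,wm optional extra signal channels (numeric, frames long).
#' @return numeric matrix of demeaned nuisance regressors with named columns.
#' @export
buildNuisance <- function(run, realignment, csf = NULL, wm = NULL) {
  stopifnot(is(run, "RoiRun"))
  realignment <- as.matrix(realignment)
  if (nrow(realignment) != nFrames(run))
    stop("realignment and run differ in frame count")
  if (ncol(realignment) != 6L) stop("realignment must have 6 columns")
  d <- rbind(0, diff(realignment))
  motion <- cbind(realignment, d, realignment^2, d^2)
  colnames(motion) <- c(paste0("mp", 1:6), paste0("mpDiff", 1:6),
                        paste0("mpSq", 1:6), paste0("mpDiffSq", 1:6))
  X <- cbind(global = rowMeans(run@signal), motion)
  if (!is.null(csf)) X <- cbind(X, csf = as.numeric(csf))
  if (!is.null(wm)) X <- cbind(X, wm = as.numeric(wm))
  if (any(!is.finite(X))) stop("non-finite nuisance values")
  sweep(X, 2, colMeans(X))
}

#' Regress nuisance signals out of a run
#'
#' The regression is fitted on retained (mask-true) frames only, so that
#' high-motion frames cannot leverage the fit, and residuals are computed
#' for all frames. Collinear nuisance columns are dropped with a warning.
#'
#' @param run an [RoiRun-class].
#' @param nuisance nuisance matrix from [buildNuisance()].
#' @param mask logical retain-mask (default: all frames).
#' @return residual [RoiRun-class].
#' @export
regressNuisance <- function(run, nuisance, mask = NULL) {
  stopifnot(is(run, "RoiRun"))
  n <- nFrames(run)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length must equal frame count")
  if (sum(mask) <= ncol(nuisance) + 1L) stop("too few retained frames for fit")
  X <- cbind(`(Intercept)` = 1, nuisance)
  qrX <- qr(X[mask, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping collinear nuisance columns: ", paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
    qrX <- qr(X[mask, , drop = FALSE])
  }
  beta <- qr.coef(qrX, run@signal[mask, , drop = FALSE])
  new("RoiRun", signal = run@signal - X %*% beta, tr = run@tr)
}

#' Interpolate over censored frames
#'
#' Censored frames are replaced by linear interpolation between the nearest
#' retained neighbours within the run; censored frames before the first or
#' after the last retained frame take the nearest retained value. The
#' interpolated frames exist only to stabilize the band-pass filter and are
#' re-censored before connectivity.
#'
#' @param run an [RoiRun-class].
#' @param mask logical retain-mask for the run.
#' @return interpolated [RoiRun-class].
#' @export
interpolateCensored <- function(run, mask) {
  stopifnot(is(run, "RoiRun"), is.logical(mask), length(mask) == nFrames(run))
  if (!any(mask)) stop("cannot interpolate a fully censored run")
  if (all(mask)) return(run)
  idx <- which(mask)
  tAll <- seq_len(nFrames(run))
  sig <- apply(run@signal, 2, function(y)
    approx(idx, y[idx], xout = tAll, method = "linear", rule = 2)$y)
  colnames(sig) <- colnames(run@signal)
  new("RoiRun", signal = sig, tr = run@tr)
}

#' Temporal band-pass filter
#'
#' Zero-phase second-order Butterworth band-pass retaining the
#' low-frequency resting-state band (default 0.009-0.08 Hz). DC and
#' high-frequency content are removed.
#'
#' @param run an [RoiRun-class].
#' @param lowHz,highHz band edges (Hz); `highHz` must be below Nyquist.
#' @return filtered [RoiRun-class].
#' @export
bandpass <- function(run, lowHz = 0.009, highHz = 0.08) {
  stopifnot(is(run, "RoiRun"))
  nyq <- 1 / (2 * run@tr)
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop("invalid band for this repetition time")
  bt <- signal::butter(2, c(lowHz, highHz) / nyq, type = "pass")
  sig <- apply(run@signal, 2, zeroPhaseFilter, filt = bt)
  colnames(sig) <- colnames(run@signal)
  new("RoiRun", signal = sig, tr = run@tr)
}

#' Clean one run end to end
#'
#' The denoising order is fixed: demean/detrend, nuisance regression
#' (fitted on retained frames), interpolation over censored frames, then
#' band-pass. The censor mask must be re-applied downstream: censored
#' frames never contribute to connectivity.
#'
#' @param run an [RoiRun-class].
#' @param realignment frames x 6 realignment matrix.
#' @param mask logical retain-mask from the censoring cascade.
#' @param lowHz,highHz band-pass edges.
#' @param csf,wm optional extra nuisance channels.
#' @return cleaned [RoiRun-class].
#' @export
cleanRun <- function(run, realignment, mask, lowHz = 0.009, highHz = 0.08,
                     csf = NULL, wm = NULL) {
  run <- demeanDetrend(run)
  nuis <- buildNuisance(run, realignment, csf = csf, wm = wm)
  run <- regressNuisance(run, nuis, mask)
  run <- interpolateCensored(run, mask)
  bandpass(run, lowHz, highHz)
}
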