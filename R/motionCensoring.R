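#' Framewise displacement from realignment parameters
#'
#' FD at frame t is the sum of the absolute backward differences of the six
#' rigid-body parameters, with the three rotations converted to arc length
#' on an assumed head radius: FD[t] = sum |d trans_i| + sum |r * d rot_i|.
#' The first frame has FD = 0 by convention.
#'
#' @param realignment frames x 6 numeric matrix; columns are three rotations
#'   (radians) followed by three translations (mm).
#' @param tr repetition time (s).
#' @param headRadius rotation-to-mm conversion radius, default 50 mm.
#' @return an [FdTrace-class] object (unfiltered).
#' @examples
#' rp <- matrix(0, 10, 6); rp[5, 4] <- 0.1
#' fdValues(computeFd(rp, tr = 1))
#' @export
computeFd <- function(realignment, tr, headRadius = 50) {
  realignment <- as.matrix(realignment)
  if (ncol(realignment) != 6L)
    stop("realignment must have 6 columns (3 rotations, 3 translations)")
  if (any(!is.finite(realignment))) stop("non-finite realignment values")
  d <- abs(diff(realignment))
  fd <- c(0, rowSums(d[, 4:6, drop = FALSE]) +
            headRadius * rowSums(d[, 1:3, drop = FALSE]))
  new("FdTrace", fd = fd, tr = tr, filtered = FALSE)
}

#' Low-pass filter an FD trace
#'
#' Zero-phase second-order Butterworth low-pass, removing the
#' high-frequency (e.g. respiratory, multiband-related) component of the
#' displacement trace before thresholding. Constant traces map to
#' themselves; the result is floored at zero.
#'
#' @param fd an [FdTrace-class].
#' @param cutoffHz low-pass cutoff (Hz), default 0.1; must be below Nyquist.
#' @return filtered [FdTrace-class].
#' @export
filterFd <- function(fd, cutoffHz = 0.1) {
  stopifnot(is(fd, "FdTrace"))
  nyq <- 1 / (2 * fd@tr)
  if (cutoffHz >= nyq) stop("cutoff must be below the Nyquist frequency")
  if (cutoffHz <= 0) stop("cutoff must be positive")
  bt <- signal::butter(2, cutoffHz / nyq, type = "low")
  y <- pmax(0, zeroPhaseFilter(fd@fd, bt))
  new("FdTrace", fd = y, tr = fd@tr, filtered = TRUE)
}

#' Censor high-motion frames
#'
#' Frames with FD strictly greater than the threshold are censored;
#' a frame exactly at the threshold is retained.
#'
#' @param fd an [FdTrace-class] (typically filtered).
#' @param thresholdMm censoring threshold in mm, default 0.2.
#' @return logical retain-mask, TRUE = keep.
#' @export
censorFrames <- function(fd, thresholdMm = 0.2) {
  stopifnot(is(fd, "FdTrace"))
  fd@fd <= thresholdMm
}

#' Remove short retained segments
#'
#' After thresholding, islands of retained frames shorter than `minContig`
#' are flipped to censored; segments of exactly `minContig` frames are kept.
#'
#' @param mask logical retain-mask for one run.
#' @param minContig minimum retained-segment length, default 5.
#' @return logical retain-mask.
#' @export
enforceContiguity <- function(mask, minContig = 5L) {
  stopifnot(is.logical(mask))
  r <- rle(mask)
  r$values[r$values & r$lengths < minContig] <- FALSE
  inverse.rle(r)
}

#' Drop runs below the frame floor
#'
#' Runs whose retained-frame count is below `minFrames` are fully censored;
#' runs with exactly `minFrames` retained frames are kept.
#'
#' @param masks list of logical retain-masks, one per run.
#' @param minFrames minimum retained frames per run, default 50.
#' @return list of masks with short runs zeroed out.
#' @export
dropShortRuns <- function(masks, minFrames = 50L) {
  lapply(masks, function(m) if (sum(m) < minFrames) m & FALSE else m)
}

#' Select the first n retained frames
#'
#' Keeps the first `n` retained frames in acquisition order across runs and
#' censors the rest, equalizing data quantity across subjects. Subjects with
#' fewer than `n` retained frames are flagged ineligible (never an error).
#'
#' @param masks list of per-run retain-masks after the cascade.
#' @param n frames to select, default 800.
#' @return a [CensorPlan-class].
#' @export
selectFirstN <- function(masks, n = 800L) {
  n <- as.integer(n)
  total <- sum(vapply(masks, sum, 0L))
  if (total < n) {
    return(new("CensorPlan", retained = masks,
               selected = lapply(masks, function(m) m & FALSE),
               eligible = FALSE, nSelect = n))
  }
  left <- n
  selected <- lapply(masks, function(m) {
    if (left <= 0L) return(m & FALSE)
    idx <- which(m)
    if (length(idx) > left) m[idx[-seq_len(left)]] <- FALSE
    left <<- left - min(length(idx), left)
    m
  })
  new("CensorPlan", retained = masks, selected = selected,
      eligible = TRUE, nSelect = n)
}

#' Full censoring cascade
#'
#' Applies, in order: FD low-pass filtering, thresholding, contiguity
#' enforcement, the per-run frame floor, and the first-n selection.
#' Censoring decisions use the filtered trace; the raw trace is kept for
#' the mean-FD covariate (mean of the filtered FD over all acquired
#' frames, pre-censoring).
#'
#' @param fdTraces list of raw [FdTrace-class] objects, one per run.
#' @param thresholdMm FD threshold (mm). @param minContig segment floor.
#' @param minFrames run floor. @param nSelect frames to select.
#' @param fdCutoffHz FD filter cutoff (Hz).
#' @return list with `plan` ([CensorPlan-class]), `meanFd` (scalar), and
#'   `filtered` (list of filtered traces).
#' @export
censorCascade <- function(fdTraces, thresholdMm = 0.2, minContig = 5L,
                          minFrames = 50L, nSelect = 800L, fdCutoffHz = 0.1) {
  filtered <- lapply(fdTraces, filterFd, cutoffHz = fdCutoffHz)
  masks <- lapply(filtered, function(f)
    enforceContiguity(censorFrames(f, thresholdMm), minContig))
  masks <- dropShortRuns(masks, minFrames)
  plan <- selectFirstN(masks, nSelect)
  meanFd <- mean(unlist(lapply(filtered, fdValues)))
  list(plan = plan, meanFd = meanFd, filtered = filtered)
}
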