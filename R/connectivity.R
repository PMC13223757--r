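#' ROI correlation matrix over selected frames
#'
#' Pearson correlations over exactly the selected retained frames,
#' concatenated across runs in acquisition order. Censored frames never
#' enter; a zero-variance ROI is an error naming the ROI.
#'
#' @param runs list of cleaned [RoiRun-class] objects.
#' @param plan a [CensorPlan-class]; its selected masks are applied.
#' @return ROI x ROI Pearson correlation matrix (diagonal 1).
#' @export
correlationMatrix <- function(runs, plan) {
  stopifnot(is(plan, "CensorPlan"))
  if (!isEligible(plan)) stop("subject is ineligible (insufficient frames)")
  if (length(runs) != length(plan@selected))
    stop("plan and runs differ in run count")
  parts <- mapply(function(run, m) {
    if (nFrames(run) != length(m)) stop("mask/run length mismatch")
    signalMatrix(run)[m, , drop = FALSE]
  }, runs, plan@selected, SIMPLIFY = FALSE)
  X <- do.call(rbind, parts)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance ROI(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  cor(X)
}

#' Fisher z-transform
#'
#' Applies atanh to the off-diagonal correlations; the diagonal is masked
#' (NA) so it can never enter an average.
#'
#' @param r ROI x ROI correlation matrix with |r| < 1 off the diagonal.
#' @return an unthresholded [ConnectivityMatrix-class].
#' @export
fisherZ <- function(r) {
  r <- as.matrix(r)
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1)) stop("off-diagonal |r| must be < 1")
  z <- atanh(r)
  diag(z) <- NA_real_
  new("ConnectivityMatrix", z = z, thresholded = FALSE)
}

#' Zero negative connectivity values
#'
#' Sets every negative Fisher-z entry to zero, leaving all positive values
#' untouched. Global-signal regression can introduce spurious negative
#' correlations, so segregation metrics are computed on the thresholded
#' matrix (zeros still count in the averages).
#'
#' @param cm a [ConnectivityMatrix-class].
#' @return thresholded [ConnectivityMatrix-class].
#' @export
thresholdNegatives <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  z <- cm@z
  z[!is.na(z) & z < 0] <- 0
  new("ConnectivityMatrix", z = z, thresholded = TRUE)
}

#' Segregation index
#'
#' S = (W - B) / W: the difference between mean within- and mean
#' between-network connectivity as a proportion of the within mean.
#' Undefined (NA, with a warning) when W <= 0.
#'
#' @param W mean within-network connectivity (z units).
#' @param B mean between-network connectivity (z units).
#' @return segregation value(s); vectorized.
#' @examples segregationIndex(0.6, 0.2)
#' @export
segregationIndex <- function(W, B) {
  out <- (W - B) / W
  bad <- !is.na(W) & W <= 0
  if (any(bad)) {
    warning("within-network mean <= 0; segregation undefined for ",
            sum(bad), " network(s)")
    out[bad] <- NA_real_
  }
  out
}

#' Within/between network means and segregation
#'
#' For each of the 13 labeled networks: W_k, the mean z over unordered ROI
#' pairs within the network; B_k, the mean z from the network's ROIs to all
#' ROIs outside it (brain-wide, including unassigned ROIs, by default, or
#' restricted to labeled networks); the pairwise between-network means
#' B_kj; and the segregation index S_k.
#'
#' @param cm thresholded [ConnectivityMatrix-class].
#' @param parc parcellation data.frame (roi_id, network) matching the
#'   matrix rows.
#' @param betweenMode "brainwide" (default) or "labeled".
#' @param meanFd optional subject mean FD to attach.
#' @return a [NetworkMetrics-class].
#' @export
networkMetrics <- function(cm, parc, betweenMode = c("brainwide", "labeled"),
                           meanFd = NA_real_) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  if (!cm@thresholded) stop("threshold the matrix before computing metrics")
  betweenMode <- match.arg(betweenMode)
  z <- cm@z
  if (nrow(z) != nrow(parc)) stop("matrix and parcellation sizes differ")
  nets <- intersect(analysisNetworks(), unique(parc$network))
  if (!length(nets)) stop("no labeled networks in parcellation")
  idx <- split(seq_len(nrow(parc)), parc$network)
  for (k in nets)
    if (length(idx[[k]]) < 2L) stop("network ", k, " has fewer than 2 ROIs")
  allIdx <- if (betweenMode == "brainwide") seq_len(nrow(parc))
            else sort(unlist(idx[nets]))
  W <- B <- setNames(numeric(length(nets)), nets)
  Bkj <- matrix(NA_real_, length(nets), length(nets), dimnames = list(nets, nets))
  for (k in nets) {
    ik <- idx[[k]]
    blk <- z[ik, ik]
    W[k] <- mean(blk[upper.tri(blk)])
    B[k] <- mean(z[ik, setdiff(allIdx, ik)])
    for (j in nets) if (j != k) Bkj[k, j] <- mean(z[ik, idx[[j]]])
  }
  new("NetworkMetrics", within = W, between = B, betweenPairs = Bkj,
      segregation = segregationIndex(W, B), betweenMode = betweenMode,
      meanFd = meanFd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a connectivity matrix as CSV
#'
#' Plain CSV with ROI ids as header row and first column, interoperable
#' with deposited correlation-matrix archives.
#'
#' @param cm [ConnectivityMatrix-class] (or plain matrix) to write.
#' @param path file path.
#' @return `readConnectivityCsv` returns a [ConnectivityMatrix-class].
#' @export
writeConnectivityCsv <- function(cm, path) {
  z <- if (is(cm, "ConnectivityMatrix")) cm@z else as.matrix(cm)
  df <- data.frame(roi_id = rownames(z) %||% colnames(z), z,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeConnectivityCsv
#' @param thresholded whether the stored matrix had negatives zeroed.
#' @export
readConnectivityCsv <- function(path, thresholded = FALSE) {
  df <- as.data.frame(data.table::fread(path))
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df[[1]]
  new("ConnectivityMatrix", z = z, thresholded = thresholded)
}
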