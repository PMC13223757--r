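#' @import methods
#' @importFrom stats approx coef cor lm lm.fit median pf pt p.adjust qt quantile
#'   rbinom rexp rnorm runif sd setNames t.test var predict resid qnorm
#' @importFrom utils head tail
NULL

#' ROI time-series run
#'
#' One resting-state run: a frames x ROIs block of mean ROI signals acquired
#' at a fixed repetition time. The unit on which cleaning and censoring act.
#'
#' @slot signal numeric matrix, frames in rows, ROIs in columns (named).
#' @slot tr repetition time in seconds.
#' @export
setClass("RoiRun", representation(signal = "matrix", tr = "numeric"))

setValidity("RoiRun", function(object) {
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a single positive number (seconds)")
  if (!is.numeric(object@signal)) return("signal must be numeric")
  if (any(!is.finite(object@signal))) return("signal contains non-finite values")
  if (is.null(colnames(object@signal))) return("signal columns must carry ROI ids")
  TRUE
})

#' Framewise-displacement trace
#'
#' Scalar per-frame head-motion summary derived from six realignment
#' parameters; rotations are converted to arc length on an assumed head
#' radius before being summed with translations.
#'
#' @slot fd per-frame displacement in mm; first frame is 0 by convention.
#' @slot tr repetition time in seconds.
#' @slot filtered whether a low-pass filter has been applied.
#' @export
setClass("FdTrace",
         representation(fd = "numeric", tr = "numeric", filtered = "logical"))

setValidity("FdTrace", function(object) {
  if (length(object@fd) < 1L) return("fd must have at least one frame")
  if (any(!is.finite(object@fd))) return("fd contains non-finite values")
  if (any(object@fd < -1e-9)) return("fd must be non-negative")
  if (length(object@filtered) != 1L) return("filtered must be a single flag")
  TRUE
})

#' Frame-censoring plan
#'
#' Boolean retain-masks per run after the censoring cascade (threshold,
#' contiguity, run floor), the final fixed-length frame selection, and the
#' subject-level eligibility flag.
#'
#' @slot retained list of logical vectors, one per run, after the cascade
#'   but before the fixed-length selection.
#' @slot selected list of logical vectors after selecting the first
#'   `nSelect` retained frames in acquisition order.
#' @slot eligible TRUE when at least `nSelect` frames survived the cascade.
#' @slot nSelect target number of frames (800 by default upstream).
#' @export
setClass("CensorPlan",
         representation(retained = "list", selected = "list",
                        eligible = "logical", nSelect = "integer"))

setValidity("CensorPlan", function(object) {
  if (length(object@retained) != length(object@selected))
    return("retained and selected must cover the same runs")
  for (i in seq_along(object@retained)) {
    r <- object@retained[[i]]; s <- object@selected[[i]]
    if (!is.logical(r) || !is.logical(s) || length(r) != length(s))
      return("per-run masks must be logical vectors of equal length")
    if (any(s & !r)) return("selection may only shrink the retained mask")
  }
  if (object@eligible && sum(vapply(object@selected, sum, 0L)) != object@nSelect)
    return("eligible plans must select exactly nSelect frames")
  TRUE
})

#' Fisher-z connectivity matrix
#'
#' Symmetric ROI x ROI matrix of Fisher-z transformed Pearson correlations.
#' The diagonal is masked (NA) and never enters any average. After
#' thresholding, negative entries are replaced by zero.
#'
#' @slot z numeric matrix with NA diagonal.
#' @slot thresholded TRUE once negatives have been zeroed.
#' @export
setClass("ConnectivityMatrix",
         representation(z = "matrix", thresholded = "logical"))

setValidity("ConnectivityMatrix", function(object) {
  z <- object@z
  if (nrow(z) != ncol(z)) return("matrix must be square")
  if (!all(is.na(diag(z)))) return("diagonal must be masked (NA)")
  off <- z[upper.tri(z)]
  if (any(!is.finite(off))) return("off-diagonal entries must be finite")
  if (max(abs(z - t(z)), na.rm = TRUE) > 1e-12) return("matrix must be symmetric")
  if (object@thresholded && any(off < 0)) return("thresholded matrix has negatives")
  TRUE
})

#' Per-network connectivity metrics
#'
#' Mean within-network z, mean between-network z (to all other ROIs), the
#' pairwise between-network means, and the segregation index
#' S = (W - B) / W for each analysis network.
#'
#' @slot within named numeric, mean within-network z per network.
#' @slot between named numeric, mean z from each network to ROIs outside it.
#' @slot betweenPairs network x network matrix of pairwise between means
#'   (NA diagonal).
#' @slot segregation named numeric, (W - B)/W; NA when W <= 0.
#' @slot betweenMode "brainwide" (between includes unassigned ROIs) or
#'   "labeled" (13 labeled networks only).
#' @slot meanFd subject mean framewise displacement, attached for
#'   downstream residualization (NA until set).
#' @export
setClass("NetworkMetrics",
         representation(within = "numeric", between = "numeric",
                        betweenPairs = "matrix", segregation = "numeric",
                        betweenMode = "character", meanFd = "numeric"))

#' Linear-model fit summary
#'
#' OLS fit with the reporting layout used for the association models:
#' per-coefficient estimate/SE/t/p, the overall F against the
#' intercept-only model, R-squared, and AIC.
#'
#' @slot response response name.
#' @slot coefficients data.frame with columns term, B, SE, t, p.
#' @slot fstat overall F statistic. @slot df1 numerator df.
#' @slot df2 denominator df. @slot pOverall overall-model p-value.
#' @slot r2 R-squared. @slot aic Gaussian AIC. @slot n observations.
#' @export
setClass("ModelFit",
         representation(response = "character", coefficients = "data.frame",
                        fstat = "numeric", df1 = "numeric", df2 = "numeric",
                        pOverall = "numeric", r2 = "numeric", aic = "numeric",
                        n = "integer"))

setValidity("ModelFit", function(object) {
  p <- nrow(object@coefficients)
  if (object@df2 != object@n - p) return("df2 must equal n - number of coefficients")
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) return("R2 out of [0, 1]")
  TRUE
})

#' Model-selection stability report
#'
#' Per-candidate summary of augmented backward elimination under bootstrap
#' resampling: full-model estimate and SE, bootstrap inclusion frequency,
#' selected-model estimate, RMSD ratio, relative conditional bias, and
#' bootstrap percentile summaries of the (zero-filled) estimates.
#'
#' @slot table data.frame, one row per candidate (forced terms first).
#' @slot nBoot number of bootstrap resamples.
#' @slot seed RNG seed used.
#' @slot nRedrawn number of degenerate resamples that were redrawn.
#' @slot selected character vector of terms in the selected model.
#' @export
setClass("SelectionReport",
         representation(table = "data.frame", nBoot = "integer",
                        seed = "integer", nRedrawn = "integer",
                        selected = "character"))

setValidity("SelectionReport", function(object) {
  tb <- object@table
  need <- c("term", "fullEstimate", "fullSE", "inclusionFreq",
            "selectedEstimate", "rmsdRatio", "relCondBias",
            "bootMedian", "bootLower", "bootUpper")
  if (!all(need %in% names(tb))) return("report table is missing columns")
  if (any(tb$inclusionFreq < 0 | tb$inclusionFreq > 100))
    return("inclusion frequencies must lie in [0, 100]")
  if (any(tb$bootLower > tb$bootMedian + 1e-9) ||
      any(tb$bootMedian > tb$bootUpper + 1e-9))
    return("bootstrap percentile bounds must be ordered")
  TRUE
})
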