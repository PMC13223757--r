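#' @describeIn RoiRun-class number of frames in the run.
setMethod("nFrames", "RoiRun", function(x) nrow(x@signal))

#' @describeIn RoiRun-class number of ROIs.
setMethod("nRois", "RoiRun", function(x) ncol(x@signal))

#' @describeIn RoiRun-class the frames x ROIs signal matrix.
setMethod("signalMatrix", "RoiRun", function(x) x@signal)

#' @describeIn RoiRun-class repetition time (s).
setMethod("repetitionTime", "RoiRun", function(x) x@tr)

#' @describeIn FdTrace-class per-frame displacement values (mm).
setMethod("fdValues", "FdTrace", function(x) x@fd)

#' @describeIn FdTrace-class repetition time (s).
setMethod("repetitionTime", "FdTrace", function(x) x@tr)

#' @describeIn CensorPlan-class per-run retain masks after the cascade.
setMethod("retainedMasks", "CensorPlan", function(x) x@retained)

#' @describeIn CensorPlan-class per-run masks after fixed-length selection.
setMethod("selectedMasks", "CensorPlan", function(x) x@selected)

#' @describeIn CensorPlan-class TRUE when the subject meets the frame floor.
setMethod("isEligible", "CensorPlan", function(x) x@eligible)

#' @describeIn ConnectivityMatrix-class the Fisher-z matrix (NA diagonal).
setMethod("zMatrix", "ConnectivityMatrix", function(x) x@z)

#' @describeIn NetworkMetrics-class mean within-network z per network.
setMethod("withinConnectivity", "NetworkMetrics", function(x) x@within)

#' @describeIn NetworkMetrics-class mean between-network z per network.
setMethod("betweenConnectivity", "NetworkMetrics", function(x) x@between)

#' @describeIn NetworkMetrics-class pairwise between-network means.
setMethod("betweenPairs", "NetworkMetrics", function(x) x@betweenPairs)

#' @describeIn NetworkMetrics-class segregation index per network.
setMethod("segregationValues", "NetworkMetrics", function(x) x@segregation)

#' @describeIn SelectionReport-class the per-candidate stability table.
setMethod("reportTable", "SelectionReport", function(x) x@table)

#' @describeIn SelectionReport-class terms retained in the selected model.
setMethod("selectedTerms", "SelectionReport", function(x) x@selected)

setMethod("show", "RoiRun", function(object) {
  cat(sprintf("RoiRun: %d frames x %d ROIs, TR = %g s\n",
              nFrames(object), nRois(object), object@tr))
})

setMethod("show", "FdTrace", function(object) {
  cat(sprintf("FdTrace: %d frames, TR = %g s, %s; mean FD = %.3f mm\n",
              length(object@fd), object@tr,
              if (object@filtered) "low-pass filtered" else "raw",
              mean(object@fd)))
})

setMethod("show", "CensorPlan", function(object) {
  kept <- vapply(object@retained, sum, 0L)
  cat(sprintf("CensorPlan: %d run(s), retained %s frames (total %d); %s\n",
              length(kept), paste(kept, collapse = "+"), sum(kept),
              if (object@eligible)
                sprintf("eligible, %d frames selected", object@nSelect)
              else "ineligible"))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@z[upper.tri(object@z)]
  cat(sprintf("ConnectivityMatrix: %d ROIs, %s; mean off-diagonal z = %.3f\n",
              nrow(object@z),
              if (object@thresholded) "negatives zeroed" else "unthresholded",
              mean(off)))
})

setMethod("show", "NetworkMetrics", function(object) {
  cat(sprintf("NetworkMetrics (%s between mode):\n", object@betweenMode))
  print(round(data.frame(within = object@within, between = object@between,
                         segregation = object@segregation), 4))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("Linear model for %s: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f, AIC = %.1f\n",
              object@response, object@df1, object@df2, object@fstat,
              object@pOverall, object@r2, object@aic))
  tb <- object@coefficients
  tb$B <- round(tb$B, 3); tb$SE <- round(tb$SE, 3)
  tb$t <- round(tb$t, 2); tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d bootstrap resamples; selected: %s\n",
              object@nBoot, paste(object@selected, collapse = ", ")))
  tb <- object@table
  num <- vapply(tb, is.numeric, TRUE)
  tb[num] <- lapply(tb[num], round, 3)
  print(tb, row.names = FALSE)
})
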