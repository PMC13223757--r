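#' @rdname RoiRun-class
#' @param object,x a package object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname RoiRun-class
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname RoiRun-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname RoiRun-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname FdTrace-class
#' @export
setGeneric("fdValues", function(x) standardGeneric("fdValues"))

#' @rdname CensorPlan-class
#' @export
setGeneric("retainedMasks", function(x) standardGeneric("retainedMasks"))

#' @rdname CensorPlan-class
#' @export
setGeneric("selectedMasks", function(x) standardGeneric("selectedMasks"))

#' @rdname CensorPlan-class
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname NetworkMetrics-class
#' @export
setGeneric("withinConnectivity", function(x) standardGeneric("withinConnectivity"))

#' @rdname NetworkMetrics-class
#' @export
setGeneric("betweenConnectivity", function(x) standardGeneric("betweenConnectivity"))

#' @rdname NetworkMetrics-class
#' @export
setGeneric("betweenPairs", function(x) standardGeneric("betweenPairs"))

#' @rdname NetworkMetrics-class
#' @export
setGeneric("segregationValues", function(x) standardGeneric("segregationValues"))

#' @rdname SelectionReport-class
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname SelectionReport-class
#' @export
setGeneric("selectedTerms", function(x) standardGeneric("selectedTerms"))
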