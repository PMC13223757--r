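#' Network labels of the 300-ROI parcellation
#'
#' The 14 functional-network labels used throughout: 13 analysis networks
#' plus "Unassigned". Network-level analyses always operate on the 13
#' labeled networks; unassigned ROIs can still contribute to brain-wide
#' between-network connectivity.
#'
#' @return character vector of the 14 labels (Unassigned last).
#' @export
networkLabels <- function() {
  c("SMd", "SMl", "CO", "AUD", "DMN", "PM", "VIS",
    "FPN", "SAL", "VAN", "DAN", "MTL", "REW", "Unassigned")
}

#' Analysis networks
#'
#' @return the 13 labeled networks (no Unassigned).
#' @export
analysisNetworks <- function() setdiff(networkLabels(), "Unassigned")

# ROI counts per network for the reference 300-ROI set. DMN, SMd and DAN
# sizes (65, 40, 14) match the whole-brain set the pipeline is designed
# around; the remaining labels are given representative sizes summing to 300.
.parcellationSizes <- c(
  SMd = 40, SMl = 9, CO = 30, AUD = 12, DMN = 65, PM = 5, VIS = 39,
  FPN = 27, SAL = 8, VAN = 12, DAN = 14, MTL = 8, REW = 13, Unassigned = 18)

#' Reference parcellation
#'
#' Builds the 300-ROI, 14-network parcellation table used by the synthetic
#' cohort and the network metrics: one row per ROI with its network label.
#'
#' @return data.frame with columns `roi_id` and `network`.
#' @examples nrow(defaultParcellation())
#' @export
defaultParcellation <- function() {
  sizes <- .parcellationSizes
  stopifnot(sum(sizes) == 300L)
  network <- rep(names(sizes), sizes)
  data.frame(roi_id = sprintf("ROI%03d", seq_along(network)),
             network = network, stringsAsFactors = FALSE)
}

#' Read / write a parcellation table
#'
#' Tab-separated table with columns `roi_id` and `network`. Every ROI must
#' carry exactly one of the 14 recognized labels.
#'
#' @param path file path.
#' @param parc parcellation data.frame.
#' @return `readParcellation` returns the validated data.frame.
#' @export
readParcellation <- function(path) {
  parc <- as.data.frame(data.table::fread(path, sep = "\t"))
  validateParcellation(parc)
  parc
}

#' @rdname readParcellation
#' @export
writeParcellation <- function(parc, path) {
  validateParcellation(parc)
  data.table::fwrite(parc, path, sep = "\t")
  invisible(path)
}

validateParcellation <- function(parc) {
  if (!all(c("roi_id", "network") %in% names(parc)))
    stop("parcellation needs roi_id and network columns")
  bad <- setdiff(unique(parc$network), networkLabels())
  if (length(bad)) stop("unknown network labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(parc$roi_id)) stop("duplicated ROI ids")
  invisible(TRUE)
}

#' Exclusion-cascade bookkeeping
#'
#' Tracks a participant exclusion cascade: the number scanned, stage-wise
#' exclusions, the final sample size, and the retention rate of the final
#' (data-quantity) stage, i.e. final / (scanned - upstream exclusions).
#'
#' @param scanned participants entering the scanning session.
#' @param exclusions named integer vector of stage-wise exclusions applied
#'   in order; the retention rate is computed for the last stage.
#' @return list with `final`, `atLastStage`, and `retentionPct`.
#' @examples
#' participantFlow(311, c(noRest = 7, behavior = 21, motion = 56))
#' @export
participantFlow <- function(scanned, exclusions) {
  stopifnot(length(exclusions) >= 1L, all(exclusions >= 0))
  remaining <- scanned - cumsum(exclusions)
  final <- remaining[length(remaining)]
  atLast <- remaining[length(remaining) - 1L]
  if (length(exclusions) == 1L) atLast <- scanned
  list(final = unname(final), atLastStage = unname(atLast),
       retentionPct = unname(100 * final / atLast))
}

#' Frames to minutes
#'
#' @param nFrames number of frames.
#' @param tr repetition time in seconds.
#' @return scan time in minutes.
#' @examples framesToMinutes(800, 1.0)
#' @export
framesToMinutes <- function(nFrames, tr) nFrames * tr / 60
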