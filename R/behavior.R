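#' Score the emotion-regulation task
#'
#' Per subject: the mean negativity rating (1-5) per condition and
#' reappraisal success = mean(LookNegative) - mean(Decrease). Positive
#' success means effective downregulation of negative affect. Missing or
#' non-response trials (NA ratings) are dropped with their count recorded;
#' a subject with zero usable trials in LookNegative or Decrease is flagged
#' excluded rather than scored.
#'
#' LookNeutral trials never enter the score; they are summarized for
#' completeness only.
#'
#' @param trials data.frame with columns `subject_id`, `condition`
#'   (LookNegative / LookNeutral / Decrease), and `rating` (1-5 or NA).
#' @return data.frame, one row per subject: condition means, usable-trial
#'   counts, `success`, `nDropped`, and `excluded`.
#' @export
reappraisalSuccess <- function(trials) {
  need <- c("subject_id", "condition", "rating")
  if (!all(need %in% names(trials))) stop("trials needs columns: ",
                                          paste(need, collapse = ", "))
  conds <- c("LookNegative", "LookNeutral", "Decrease")
  bad <- setdiff(unique(trials$condition), conds)
  if (length(bad)) stop("unknown conditions: ", paste(bad, collapse = ", "))
  out <- lapply(split(trials, trials$subject_id), function(tt) {
    usable <- tt[!is.na(tt$rating), , drop = FALSE]
    m <- vapply(conds, function(cc)
      mean(usable$rating[usable$condition == cc]), 0)
    n <- vapply(conds, function(cc) sum(usable$condition == cc), 0L)
    data.frame(subject_id = tt$subject_id[1],
               meanLookNegative = m[1], meanLookNeutral = m[2],
               meanDecrease = m[3],
               nLookNegative = n[1], nLookNeutral = n[2], nDecrease = n[3],
               success = m[1] - m[3],
               nDropped = nrow(tt) - nrow(usable),
               excluded = n[1] == 0L || n[3] == 0L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$success[res$excluded] <- NA_real_
  res
}
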