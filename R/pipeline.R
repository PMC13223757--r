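#' Pipeline configuration
#'
#' All numeric settings of the processing and analysis stages, serialized
#' verbatim into every output manifest so a run is reproducible from its
#' outputs.
#'
#' @slot dataDir cohort directory. @slot outDir output directory.
#' @slot tr repetition time (s).
#' @slot fdThreshold censoring threshold (mm). @slot fdCutoffHz FD filter
#'   cutoff (Hz). @slot minContig retained-segment floor. @slot minRun
#'   per-run frame floor. @slot nFrames frames selected per subject.
#' @slot bandLow,bandHigh band-pass edges (Hz).
#' @slot betweenMode "brainwide" or "labeled".
#' @slot tau change-in-estimate threshold for selection.
#' @slot nBoot bootstrap resamples. @slot seed analysis seed.
#' @slot quadraticInteractions interact connectivity with quadratic age.
#' @export
setClass("PipelineConfig", representation(
  dataDir = "character", outDir = "character", tr = "numeric",
  fdThreshold = "numeric", fdCutoffHz = "numeric", minContig = "integer",
  minRun = "integer", nFrames = "integer", bandLow = "numeric",
  bandHigh = "numeric", betweenMode = "character", tau = "numeric",
  nBoot = "integer", seed = "integer", quadraticInteractions = "logical"),
  prototype = list(dataDir = "cohort", outDir = "out", tr = 1.0,
                   fdThreshold = 0.2, fdCutoffHz = 0.1, minContig = 5L,
                   minRun = 50L, nFrames = 800L, bandLow = 0.009,
                   bandHigh = 0.08, betweenMode = "brainwide", tau = 0.05,
                   nBoot = 1000L, seed = 1L,
                   quadraticInteractions = FALSE))

setValidity("PipelineConfig", function(object) {
  if (object@fdThreshold <= 0 || object@minContig <= 0 ||
      object@minRun <= 0 || object@nFrames <= 0)
    return("thresholds must be positive")
  if (object@bandLow >= object@bandHigh) return("bandLow must be below bandHigh")
  if (!object@betweenMode %in% c("brainwide", "labeled"))
    return("betweenMode must be 'brainwide' or 'labeled'")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param ... slots by name.
#' @export
pipelineConfig <- function(...) new("PipelineConfig", ...)

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a [PipelineConfig-class].
#' @return `readPipelineConfig` returns a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  intSlots <- c("minContig", "minRun", "nFrames", "nBoot", "seed")
  for (nm in intersect(names(vals), intSlots)) vals[[nm]] <- as.integer(vals[[nm]])
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  nms <- slotNames("PipelineConfig")
  vals <- lapply(nms, function(nm) slot(config, nm))
  names(vals) <- nms
  yaml::write_yaml(vals, path)
  invisible(path)
}

configAsList <- function(config) {
  nms <- slotNames("PipelineConfig")
  setNames(lapply(nms, function(nm) slot(config, nm)), nms)
}

writeManifest <- function(config, dir, extra = list()) {
  jsonlite::write_json(
    c(list(config = configAsList(config),
           package = as.character(utils::packageVersion("netsegfc"))),
      extra),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Pipeline stages
#'
#' `runSimulate` writes a synthetic cohort to `config@dataDir`.
#' `runPreprocess` computes FD, the censoring cascade, and cleaned runs
#' for every subject, writing censor summaries and an exclusions report.
#' `runConnectivity` builds per-subject thresholded Fisher-z matrices and
#' network metrics over the selected frames. `runAnalyze` scores behavior
#' and fits the association models (per-network segregation models with
#' FDR, within/between models for the networks significant there, and the
#' seed-network between-pair selection model with bootstrap stability).
#' `runReport` writes a plain-text summary, a ground-truth recovery table
#' when the truth file is present, and diagnostic figures. `runAll` chains
#' every stage.
#'
#' @param config a [PipelineConfig-class].
#' @param spec a [CohortSpec-class] (simulate only).
#' @return each stage invisibly returns its main products.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config, spec = cohortSpec()) {
  gt <- generateCohort(spec, config@dataDir)
  writeManifest(config, config@dataDir,
                list(stage = "simulate", seed = spec@seed))
  invisible(gt)
}

#' @rdname pipeline
#' @export
runPreprocess <- function(config) {
  cohort <- loadCohort(config@dataDir)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  cleanDir <- file.path(config@outDir, "cleaned")
  dir.create(cleanDir, showWarnings = FALSE)
  rows <- list()
  for (sid in cohort$subjects) {
    sub <- readSubjectRuns(config@dataDir, sid, config@tr)
    fdTraces <- lapply(sub$motion, computeFd, tr = config@tr)
    casc <- censorCascade(fdTraces, thresholdMm = config@fdThreshold,
                          minContig = config@minContig,
                          minFrames = config@minRun,
                          nSelect = config@nFrames,
                          fdCutoffHz = config@fdCutoffHz)
    plan <- casc$plan
    retained <- vapply(retainedMasks(plan), sum, 0L)
    rows[[sid]] <- data.frame(subject_id = sid, meanFd = casc$meanFd,
                              retained = sum(retained),
                              eligible = isEligible(plan))
    sdir <- file.path(cleanDir, sid)
    dir.create(sdir, showWarnings = FALSE)
    masks <- do.call(rbind, lapply(seq_along(retainedMasks(plan)), function(r)
      data.frame(run = r, frame = seq_along(retainedMasks(plan)[[r]]),
                 retained = retainedMasks(plan)[[r]],
                 selected = selectedMasks(plan)[[r]])))
    data.table::fwrite(masks, file.path(sdir, "censor_masks.tsv"), sep = "\t")
    if (isEligible(plan)) {
      for (r in seq_along(sub$runs)) {
        cleaned <- cleanRun(sub$runs[[r]], sub$motion[[r]],
                            retainedMasks(plan)[[r]],
                            lowHz = config@bandLow, highHz = config@bandHigh)
        data.table::fwrite(as.data.frame(round(signalMatrix(cleaned), 5)),
                           file.path(sdir, sprintf("run-%02d_cleaned.tsv", r)),
                           sep = "\t")
      }
      jsonlite::write_json(
        list(regressors = c("global", "motion6", "motionDiff6",
                            "motionSq12"),
             band = c(config@bandLow, config@bandHigh),
             fdCutoffHz = config@fdCutoffHz,
             fitOnRetainedFrames = TRUE),
        file.path(sdir, "cleaning.json"), auto_unbox = TRUE)
    }
  }
  summary <- do.call(rbind, rows)
  data.table::fwrite(summary, file.path(config@outDir, "censor_summary.csv"))
  excl <- summary[!summary$eligible, , drop = FALSE]
  data.table::fwrite(excl, file.path(config@outDir, "exclusions.csv"))
  writeManifest(config, config@outDir, list(stage = "preprocess"))
  invisible(summary)
}

#' @rdname pipeline
#' @export
runConnectivity <- function(config) {
  cohort <- loadCohort(config@dataDir)
  summary <- as.data.frame(data.table::fread(
    file.path(config@outDir, "censor_summary.csv")))
  cleanDir <- file.path(config@outDir, "cleaned")
  connDir <- file.path(config@outDir, "connectivity")
  dir.create(connDir, showWarnings = FALSE)
  rows <- list()
  for (sid in summary$subject_id[summary$eligible]) {
    sdir <- file.path(cleanDir, sid)
    masks <- as.data.frame(data.table::fread(
      file.path(sdir, "censor_masks.tsv")))
    runIds <- sort(unique(masks$run))
    runs <- lapply(runIds, function(r)
      new("RoiRun", signal = as.matrix(data.table::fread(
        file.path(sdir, sprintf("run-%02d_cleaned.tsv", r)))), tr = config@tr))
    plan <- new("CensorPlan",
                retained = lapply(runIds, function(r)
                  masks$retained[masks$run == r]),
                selected = lapply(runIds, function(r)
                  masks$selected[masks$run == r]),
                eligible = TRUE, nSelect = config@nFrames)
    cm <- thresholdNegatives(fisherZ(correlationMatrix(runs, plan)))
    writeConnectivityCsv(cm, file.path(connDir, paste0(sid, "_zmatrix.csv")))
    met <- networkMetrics(cm, cohort$parc, betweenMode = config@betweenMode,
                          meanFd = summary$meanFd[summary$subject_id == sid])
    nets <- analysisNetworks()
    pair <- betweenPairs(met)
    row <- data.frame(subject_id = sid, meanFd = met@meanFd,
                      t(setNames(withinConnectivity(met), paste0("W_", nets))),
                      t(setNames(betweenConnectivity(met), paste0("B_", nets))),
                      t(setNames(segregationValues(met), paste0("S_", nets))))
    for (j in setdiff(nets, "SMd"))
      row[[paste0("Bpair_SMd_", j)]] <- pair["SMd", j]
    rows[[sid]] <- row
  }
  metrics <- do.call(rbind, rows)
  data.table::fwrite(metrics, file.path(config@outDir, "network_metrics.csv"))
  writeManifest(config, config@outDir, list(stage = "connectivity"))
  invisible(metrics)
}

#' @rdname pipeline
#' @export
runAnalyze <- function(config) {
  metrics <- as.data.frame(data.table::fread(
    file.path(config@outDir, "network_metrics.csv")))
  cohort <- loadCohort(config@dataDir)
  scored <- reappraisalSuccess(cohort$behavior)
  data.table::fwrite(scored, file.path(config@outDir, "behavior_scored.csv"))
  df <- merge(metrics, scored[!scored$excluded,
                              c("subject_id", "success")], by = "subject_id")
  df <- merge(df, cohort$covariates[, c("subject_id", "age")],
              by = "subject_id")
  if (nrow(df) < 10L) stop("too few analyzable subjects (", nrow(df), ")")
  nets <- analysisNetworks()
  successZ <- standardize(df$success)
  ageZ <- standardize(df$age)
  resid <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    apply(m, 2, residualizeOnFd, meanFd = df$meanFd)
  }
  segR <- resid(paste0("S_", nets)); colnames(segR) <- nets
  wR <- resid(paste0("W_", nets)); colnames(wR) <- nets
  bR <- resid(paste0("B_", nets)); colnames(bR) <- nets
  segres <- segregationModels(successZ, segR, ageZ)
  data.table::fwrite(segres$summary,
                     file.path(config@outDir, "segregation_models.csv"))
  sig <- segres$summary$network[segres$summary$pModelFdr < 0.05]
  wb <- withinBetweenModels(successZ, wR[, sig, drop = FALSE],
                            bR[, sig, drop = FALSE], ageZ,
                            quadraticInteractions = config@quadraticInteractions)
  wbTab <- do.call(rbind, lapply(names(wb), function(k)
    cbind(network = k, wb[[k]]@coefficients)))
  data.table::fwrite(wbTab, file.path(config@outDir, "within_between_models.csv"))
  pairCols <- grep("^Bpair_SMd_", names(df), value = TRUE)
  bp <- resid(pairCols)
  colnames(bp) <- sub("^Bpair_SMd_", "", pairCols)
  report <- seedBetweenModel(successZ, resid("W_SMd")[, 1], bp, ageZ,
                             seedNetwork = "SMd", tau = config@tau,
                             nBoot = config@nBoot, seed = config@seed)
  data.table::fwrite(reportTable(report),
                     file.path(config@outDir, "smd_selection_report.csv"))
  jsonlite::write_json(
    list(selected = selectedTerms(report), nBoot = report@nBoot,
         significantNetworks = sig),
    file.path(config@outDir, "analysis.json"), auto_unbox = TRUE, digits = NA)
  writeManifest(config, config@outDir, list(stage = "analyze"))
  invisible(list(segregation = segres, withinBetween = wb,
                 selection = report, data = df))
}

#' @rdname pipeline
#' @export
runReport <- function(config) {
  res <- runAnalyze(config)
  df <- res$data
  cohort <- loadCohort(config@dataDir)
  lines <- c(
    "netsegfc pipeline summary",
    sprintf("analyzable subjects: %d", nrow(df)),
    sprintf("mean reappraisal success: %.3f (SD %.3f)",
            mean(df$success), sd(df$success)),
    sprintf("FDR-significant networks: %s",
            paste(res$segregation$summary$network[
              res$segregation$summary$pModelFdr < 0.05], collapse = ", ")),
    sprintf("selected model terms: %s",
            paste(selectedTerms(res$selection), collapse = ", ")))
  gt <- cohort$groundTruth
  if (!is.null(gt$trueSegregation)) {
    ts <- as.data.frame(gt$trueSegregation)
    keep <- match(df$subject_id, gt$subjects)
    rec <- vapply(analysisNetworks(), function(k)
      cor(ts[[k]][keep], df[[paste0("S_", k)]]), 0)
    recTab <- data.frame(network = analysisNetworks(),
                         recoveryCor = round(rec, 3))
    data.table::fwrite(recTab, file.path(config@outDir, "recovery.csv"))
    lines <- c(lines, sprintf("median truth-recovery correlation: %.3f",
                              median(rec)))
  }
  writeLines(lines, file.path(config@outDir, "summary.txt"))
  grDevices::pdf(file.path(config@outDir, "figures.pdf"), width = 9, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2))
  plot(df$age, df$success, pch = 19, col = "grey40",
       xlab = "age (years)", ylab = "reappraisal success",
       main = "success vs age")
  az <- standardize(df$age)
  fit <- lm(df$success ~ az + I(az^2))
  ord <- order(df$age)
  graphics::lines(df$age[ord], predict(fit)[ord], col = "firebrick", lwd = 2)
  plot(df$S_DMN, df$success, pch = 19, col = "grey40",
       xlab = "DMN segregation", ylab = "reappraisal success",
       main = "success vs DMN segregation")
  graphics::abline(lm(df$success ~ df$S_DMN), col = "firebrick", lwd = 2)
  invisible(lines)
}

#' @rdname pipeline
#' @export
runAll <- function(config, spec = cohortSpec()) {
  runSimulate(config, spec)
  runPreprocess(config)
  runConnectivity(config)
  runReport(config)
}
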