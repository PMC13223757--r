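#' Synthetic-cohort specification
#'
#' All knobs of the synthetic study: cohort size and age range, acquisition
#' geometry (TR, runs, frames), the planted network-covariance targets
#' (Fisher-z within/between), subject-level variability, planted behavioral
#' effects, motion model, and nuisance components. Defaults are the study
#' conditions the package is designed around: 227 subjects aged 6-80,
#' TR 1 s, one 900-frame run, within-network z 0.5 against between-network
#' z 0.1, a planted DMN segregation effect of 0.35 (standardized), a
#' quadratic age effect of -0.25, and mean reappraisal success 1.02 on a
#' 0.75 scale.
#'
#' @slot nSubjects cohort size.
#' @slot ageRange min/max age in years, within [6, 80].
#' @slot tr repetition time (s). @slot nFramesPerRun frames per run.
#' @slot nRuns runs per subject.
#' @slot withinZ named target within-network Fisher z per network label.
#' @slot betweenZ target between-network Fisher z (scalar).
#' @slot subjectSdWithin,subjectSdBetween,subjectSdBetweenPair SDs of the
#'   subject-level deviations of within-z, the shared between-z level, and
#'   each network pair's between-z.
#' @slot plantedBetaSeg named standardized effects of network segregation
#'   on reappraisal success.
#' @slot plantedBetaWithin,plantedBetaBetweenPair named standardized
#'   effects of within-network connectivity (by network) and pairwise
#'   between connectivity (names like "SMd-SMl").
#' @slot ageBetaLinear,ageBetaQuad standardized age effects (the quadratic
#'   applies to squared standardized age).
#' @slot noiseSd residual SD of the standardized success latent; NA means
#'   "complete to unit variance".
#' @slot successMean,successSd location and scale mapping the standardized
#'   latent to the rating-difference scale.
#' @slot lookNegBaseline,lookNeutBaseline latent rating baselines.
#' @slot ratingNoiseSd trial-level latent rating noise.
#' @slot nTrialsPerCondition trials per condition (20/20/20 design).
#' @slot motionSpikeRate per-frame spike probability (cohort base rate).
#' @slot motionSpikeScale spike magnitude (mm).
#' @slot motionWalkSd per-frame SD of the slow random-walk baseline (mm).
#' @slot fdBetaBetween motion-confound slope: how strongly standardized
#'   mean FD inflates measured between-network z.
#' @slot measurementSdW,measurementSdB sampling-noise SDs of measured
#'   within-z and pairwise between-z at the fixed frame budget.
#' @slot globalAmp,driftAmp,artifactGain amplitudes of the shared global
#'   signal, per-ROI linear drift, and motion-spike artifact injected into
#'   the simulated time series (all removable by the cleaning stages).
#' @slot seed cohort RNG seed.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer", ageRange = "numeric", tr = "numeric",
  nFramesPerRun = "integer", nRuns = "integer",
  withinZ = "numeric", betweenZ = "numeric",
  subjectSdWithin = "numeric", subjectSdBetween = "numeric",
  subjectSdBetweenPair = "numeric",
  plantedBetaSeg = "numeric", plantedBetaWithin = "numeric",
  plantedBetaBetweenPair = "numeric",
  ageBetaLinear = "numeric", ageBetaQuad = "numeric", noiseSd = "numeric",
  successMean = "numeric", successSd = "numeric",
  lookNegBaseline = "numeric", lookNeutBaseline = "numeric",
  ratingNoiseSd = "numeric", nTrialsPerCondition = "integer",
  motionSpikeRate = "numeric", motionSpikeScale = "numeric",
  motionWalkSd = "numeric", fdBetaBetween = "numeric",
  measurementSdW = "numeric", measurementSdB = "numeric",
  globalAmp = "numeric", driftAmp = "numeric", artifactGain = "numeric",
  seed = "integer"),
  prototype = list(
    nSubjects = 227L, ageRange = c(6, 80), tr = 1.0,
    nFramesPerRun = 900L, nRuns = 1L,
    withinZ = setNames(rep(0.5, 14L),
                       c("SMd", "SMl", "CO", "AUD", "DMN", "PM", "VIS",
                         "FPN", "SAL", "VAN", "DAN", "MTL", "REW",
                         "Unassigned")),
    betweenZ = 0.1,
    subjectSdWithin = 0.10, subjectSdBetween = 0.01,
    subjectSdBetweenPair = 0.05,
    plantedBetaSeg = c(DMN = 0.35),
    plantedBetaWithin = setNames(numeric(0), character(0)),
    plantedBetaBetweenPair = setNames(numeric(0), character(0)),
    ageBetaLinear = 0, ageBetaQuad = -0.25, noiseSd = NA_real_,
    successMean = 1.02, successSd = 0.75,
    lookNegBaseline = 3.5, lookNeutBaseline = 1.5, ratingNoiseSd = 0.6,
    nTrialsPerCondition = 20L,
    motionSpikeRate = 0.02, motionSpikeScale = 0.6, motionWalkSd = 0.01,
    fdBetaBetween = 0.013, measurementSdW = 0.02, measurementSdB = 0.005,
    globalAmp = 1.0, driftAmp = 0.5, artifactGain = 3.0,
    seed = 1L))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L) return("empty cohort")
  ar <- object@ageRange
  if (length(ar) != 2L || ar[1] > ar[2] || ar[1] < 6 || ar[2] > 80)
    return("ageRange must be [min, max] within [6, 80]")
  if (!all(networkLabels() %in% names(object@withinZ)))
    return("withinZ must name every network label")
  if (any(object@withinZ <= object@betweenZ))
    return("withinZ must exceed betweenZ for every network")
  if (object@betweenZ < 0) return("betweenZ must be non-negative")
  total <- object@nFramesPerRun * object@nRuns
  expectedCensored <- total * min(1, 3 * object@motionSpikeRate)
  if (total - expectedCensored < 800)
    return("frame budget must cover 800 frames plus expected censoring")
  badPair <- vapply(names(object@plantedBetaBetweenPair), function(nm)
    length(strsplit(nm, "-", fixed = TRUE)[[1]]) != 2L, TRUE)
  if (any(badPair)) return("pair effect names must look like 'SMd-SMl'")
  TRUE
})

#' Construct a cohort specification
#'
#' @param nSubjects,ageRange,tr,nFramesPerRun,nRuns,withinZ,betweenZ,seed
#'   see [CohortSpec-class]; `withinZ` may be a single number applied to
#'   every network.
#' @param ... any other [CohortSpec-class] slot by name.
#' @return a validated [CohortSpec-class].
#' @examples cohortSpec(nSubjects = 10, seed = 7)
#' @export
cohortSpec <- function(nSubjects = 227L, ageRange = c(6, 80), tr = 1.0,
                       nFramesPerRun = 900L, nRuns = 1L,
                       withinZ = 0.5, betweenZ = 0.1, seed = 1L, ...) {
  if (length(withinZ) == 1L)
    withinZ <- setNames(rep(withinZ, length(networkLabels())), networkLabels())
  new("CohortSpec", nSubjects = as.integer(nSubjects), ageRange = ageRange,
      tr = tr, nFramesPerRun = as.integer(nFramesPerRun),
      nRuns = as.integer(nRuns), withinZ = withinZ, betweenZ = betweenZ,
      seed = as.integer(seed), ...)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: n = %d, ages %g-%g, %d run(s) x %d frames",
                     " @ TR %g s, seed %d\n"),
              object@nSubjects, object@ageRange[1], object@ageRange[2],
              object@nRuns, object@nFramesPerRun, object@tr, object@seed))
  cat(sprintf("  within z (mean) %.2f vs between z %.2f; planted effects: %s\n",
              mean(object@withinZ), object@betweenZ,
              paste(c(sprintf("seg %s=%.2f", names(object@plantedBetaSeg),
                              object@plantedBetaSeg),
                      sprintf("age2=%.2f", object@ageBetaQuad)),
                    collapse = ", ")))
})

#' Cohort ground truth
#'
#' Everything the generator knows before noise: per-subject true
#' within/between Fisher z per network, true segregation, the true
#' reappraisal-success values, expected mean FD, and the planted
#' coefficients. Reproducible from the spec's seed.
#'
#' @slot ages,sex,motionPropensity,spikeRate,meanFdExpected per-subject.
#' @slot withinZ n x 14 matrix of subject within-z per network label.
#' @slot betweenPairZ 14 x 14 x n array of subject pairwise between-z.
#' @slot trueWithin,trueBetween,trueSegregation n x 13 matrices over the
#'   analysis networks (between is brain-wide).
#' @slot trueSuccess per-subject success before behavioral noise.
#' @slot planted list of the planted coefficients.
#' @slot seed integer seed the truth was drawn under.
#' @export
setClass("GroundTruth", representation(
  ages = "numeric", sex = "character", motionPropensity = "numeric",
  spikeRate = "numeric", meanFdExpected = "numeric",
  withinZ = "matrix", betweenPairZ = "array",
  trueWithin = "matrix", trueBetween = "matrix",
  trueSegregation = "matrix", trueSuccess = "numeric",
  planted = "list", seed = "integer"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d subjects (seed %d); mean true segregation %.3f\n",
              length(object@ages), object@seed,
              mean(object@trueSegregation)))
})

#' Sample subject ages
#'
#' Uniform draws within the spec's age range, deterministic under the
#' spec's seed.
#'
#' @param spec a [CohortSpec-class].
#' @return numeric vector of ages (years).
#' @export
sampleAges <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  if (spec@nSubjects < 1L) stop("empty cohort")
  set.seed(seedFor(spec@seed, 0L, 1L))
  runif(spec@nSubjects, spec@ageRange[1], spec@ageRange[2])
}

#' Draw the cohort ground truth
#'
#' Samples ages, motion propensity, and subject-level network covariance
#' targets (within-z per network, between-z per network pair) around the
#' spec's planted values, then builds the true reappraisal-success values:
#' a standardized latent combining linear and quadratic age, the planted
#' segregation / within / pairwise-between effects (each on its
#' standardized true metric), and Gaussian noise completing the latent to
#' unit variance when `noiseSd` is NA, mapped through
#' `successMean + successSd * latent`.
#'
#' True network metrics are independent of motion; motion corrupts only
#' the *measured* metrics downstream, which is what FD residualization is
#' for.
#'
#' @param spec a [CohortSpec-class].
#' @param parc parcellation (defaults to [defaultParcellation()]); ROI
#'   counts weight the brain-wide between means.
#' @return a [GroundTruth-class].
#' @export
sampleGroundTruth <- function(spec, parc = defaultParcellation()) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nSubjects
  labels <- networkLabels()
  nets <- analysisNetworks()
  sizes <- table(factor(parc$network, levels = labels))
  ages <- sampleAges(spec)
  set.seed(seedFor(spec@seed, 0L, 2L))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  u <- rnorm(n)
  spikeRate <- pmin(0.2, spec@motionSpikeRate * exp(0.5 * u))
  # baseline walk FD plus two censorable frames per spike
  meanFdExpected <- 6 * spec@motionWalkSd * sqrt(2 / pi) +
    2 * spec@motionSpikeScale * spikeRate

  wz <- sapply(labels, function(k)
    spec@withinZ[k] + spec@subjectSdWithin * rnorm(n))
  wz <- matrix(wz, n, length(labels), dimnames = list(NULL, labels))
  bzBase <- spec@betweenZ + spec@subjectSdBetween * rnorm(n)
  bz <- array(NA_real_, c(length(labels), length(labels), n),
              dimnames = list(labels, labels, NULL))
  for (a in seq_along(labels)) for (b in seq_along(labels)) if (a < b) {
    v <- bzBase + spec@subjectSdBetweenPair * rnorm(n)
    bz[a, b, ] <- v; bz[b, a, ] <- v
  }
  # keep each subject's covariance targets ordered: between below within
  for (i in seq_len(n)) {
    cap <- outer(wz[i, ], wz[i, ], pmin) - 0.05
    bz[, , i] <- pmin(pmax(bz[, , i], 0.01), cap)
  }
  wz <- pmax(wz, 0.1)

  w13 <- wz[, nets, drop = FALSE]
  b13 <- sapply(nets, function(k) {
    others <- setdiff(labels, k)
    wts <- as.numeric(sizes[others])
    apply(bz[k, others, , drop = FALSE], 3, function(v) sum(v * wts) / sum(wts))
  })
  b13 <- matrix(b13, n, length(nets), dimnames = list(NULL, nets))
  s13 <- (w13 - b13) / w13

  # a planted effect on a degenerate (constant) vector contributes nothing
  zOr0 <- function(x) if (length(x) < 2L || sd(x) == 0) rep(0, length(x))
                      else standardize(x)
  zAge <- zOr0(ages)
  q <- zAge^2 - mean(zAge^2)
  d <- spec@ageBetaLinear * zAge + spec@ageBetaQuad * q
  for (k in names(spec@plantedBetaSeg))
    d <- d + spec@plantedBetaSeg[k] * zOr0(s13[, k])
  for (k in names(spec@plantedBetaWithin))
    d <- d + spec@plantedBetaWithin[k] * zOr0(w13[, k])
  for (nm in names(spec@plantedBetaBetweenPair)) {
    pr <- strsplit(nm, "-", fixed = TRUE)[[1]]
    d <- d + spec@plantedBetaBetweenPair[nm] * zOr0(bz[pr[1], pr[2], ])
  }
  noiseSd <- spec@noiseSd
  if (is.na(noiseSd)) noiseSd <- sqrt(max(0.05, 1 - var(d)))
  latent <- d + noiseSd * rnorm(n)
  trueSuccess <- spec@successMean + spec@successSd * latent

  new("GroundTruth", ages = ages, sex = sex, motionPropensity = u,
      spikeRate = spikeRate, meanFdExpected = meanFdExpected,
      withinZ = wz, betweenPairZ = bz, trueWithin = w13, trueBetween = b13,
      trueSegregation = s13, trueSuccess = trueSuccess,
      planted = list(betaSeg = as.list(spec@plantedBetaSeg),
                     betaWithin = as.list(spec@plantedBetaWithin),
                     betaBetweenPair = as.list(spec@plantedBetaBetweenPair),
                     ageBetaLinear = spec@ageBetaLinear,
                     ageBetaQuad = spec@ageBetaQuad,
                     noiseSd = noiseSd),
      seed = spec@seed)
}

#' Simulate a realignment trace
#'
#' Slow random-walk baseline on all six parameters plus sparse one-frame
#' displacement spikes (random translation axis, random sign, magnitude
#' `motionSpikeScale`), which produce framewise-displacement excursions at
#' the spike frame and the frame after it. Columns are three rotations
#' (radians) then three translations (mm).
#'
#' @param spec a [CohortSpec-class].
#' @param subjectSeed per-subject seed.
#' @param spikeRate per-frame spike probability (default the spec's base
#'   rate).
#' @return list with one element per run: `trace` (frames x 6) and
#'   `spikes` (spike frame indices).
#' @export
simulateMotion <- function(spec, subjectSeed, spikeRate = spec@motionSpikeRate) {
  lapply(seq_len(spec@nRuns), function(r) {
    set.seed(seedFor(subjectSeed, r, 4L))
    nf <- spec@nFramesPerRun
    rot <- sapply(1:3, function(j) cumsum(rnorm(nf, 0, spec@motionWalkSd / 50)))
    trans <- sapply(1:3, function(j) cumsum(rnorm(nf, 0, spec@motionWalkSd)))
    trace <- cbind(rot, trans)
    colnames(trace) <- c("rot_x", "rot_y", "rot_z",
                         "trans_x", "trans_y", "trans_z")
    spikes <- which(runif(nf) < spikeRate)
    for (t in spikes) {
      j <- sample(4:6, 1L)
      trace[t, j] <- trace[t, j] + sample(c(-1, 1), 1L) * spec@motionSpikeScale
    }
    list(trace = trace, spikes = spikes)
  })
}

#' Simulate ROI time-series runs
#'
#' Draws zero-mean Gaussian frames with the subject's block covariance
#' (within-network correlation tanh(within-z), pairwise between-network
#' correlation tanh(between-z)), then injects a shared global component, a
#' per-ROI linear drift, and, at motion-spike frames, a large shared
#' artifact -- so the cleaning and censoring stages have real structure to
#' remove. The target covariance must be positive definite.
#'
#' @param spec a [CohortSpec-class].
#' @param parc parcellation data.frame.
#' @param withinZ named within-z targets (length 14) for this subject.
#' @param betweenPairZ 14 x 14 symmetric between-z targets.
#' @param subjectSeed per-subject seed.
#' @param motion optional output of [simulateMotion()]; its spike frames
#'   receive the artifact.
#' @return list of [RoiRun-class] objects.
#' @export
simulateRoiTimeseries <- function(spec, parc, withinZ, betweenPairZ,
                                  subjectSeed, motion = NULL) {
  labels <- networkLabels()
  netIdx <- match(parc$network, labels)
  nRoi <- nrow(parc)
  R <- tanh(betweenPairZ)[netIdx, netIdx]
  same <- outer(netIdx, netIdx, "==")
  R[same] <- tanh(withinZ)[netIdx[row(R)[same]]]
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e)
    stop("target block covariance is not positive definite; ",
         "lower the within/between z targets", call. = FALSE))
  lapply(seq_len(spec@nRuns), function(r) {
    set.seed(seedFor(subjectSeed, r, 5L))
    nf <- spec@nFramesPerRun
    X <- matrix(rnorm(nf * nRoi), nf, nRoi) %*% ch
    if (spec@globalAmp > 0)
      X <- X + spec@globalAmp * rnorm(nf)
    if (spec@driftAmp > 0)
      X <- X + outer(seq(-0.5, 0.5, length.out = nf),
                     rnorm(nRoi, 0, spec@driftAmp))
    if (!is.null(motion) && spec@artifactGain > 0) {
      spikes <- motion[[r]]$spikes
      if (length(spikes)) {
        # spatially heterogeneous loadings (not a pure global component, so
        # global-signal regression cannot absorb it) with a spin-history
        # tail decaying over the frames after the displacement itself
        w <- rnorm(nRoi)
        amp <- spec@artifactGain * spec@motionSpikeScale
        decay <- c(1, 0.6, 0.35, 0.2)
        for (d in seq_along(decay)) {
          at <- spikes + d - 1L
          at <- at[at <= nf]
          if (length(at))
            X[at, ] <- X[at, ] + decay[d] * amp *
              outer(rnorm(length(at), 1, 0.2), w)
        }
      }
    }
    colnames(X) <- parc$roi_id
    new("RoiRun", signal = X, tr = spec@tr)
  })
}

#' Simulate behavioral trials for one subject
#'
#' 20 trials per condition. Look-Negative trials are drawn around a fixed
#' negative latent baseline, Look-Neutral around a low baseline, and
#' Decrease around the Look-Negative baseline minus the subject's true
#' reappraisal success. Trial-level Gaussian noise is added on the latent
#' scale, then ratings are rounded (half away from zero) and clipped to
#' the 1-5 integer scale.
#'
#' @param spec a [CohortSpec-class].
#' @param trueSuccess the subject's true success value.
#' @param subjectSeed per-subject seed.
#' @return data.frame with trial, condition, rating (trial order shuffled).
#' @export
simulateBehavior <- function(spec, trueSuccess, subjectSeed) {
  set.seed(seedFor(subjectSeed, 0L, 6L))
  k <- spec@nTrialsPerCondition
  latent <- c(rep(spec@lookNegBaseline, k),
              rep(spec@lookNeutBaseline, k),
              rep(spec@lookNegBaseline - trueSuccess, k))
  condition <- rep(c("LookNegative", "LookNeutral", "Decrease"), each = k)
  rating <- pmin(5, pmax(1, roundHalfUp(latent + spec@ratingNoiseSd *
                                          rnorm(3 * k))))
  ord <- sample.int(3 * k)
  data.frame(trial = seq_len(3 * k), condition = condition[ord],
             rating = rating[ord])
}

#' Metric-level synthetic cohort
#'
#' The generator's measurement layer without the time-series detour: for
#' each subject it returns the *measured* network metrics -- the true
#' within/between z plus frame-budget sampling noise and a motion confound
#' that inflates measured between-network connectivity in proportion to
#' standardized mean FD (inducing the negative segregation-FD correlation
#' that FD residualization is designed to remove) -- together with ages,
#' mean FD, and observed reappraisal success scored from simulated trials.
#'
#' @param spec a [CohortSpec-class].
#' @param parc parcellation data.frame.
#' @return list with `gt` ([GroundTruth-class]), and data: `age`, `meanFd`,
#'   `success` (observed), `successTrue`, `seg`, `within`, `between`
#'   (n x 13 measured matrices), and `betweenPairs` (13 x 13 x n).
#' @export
simulateMetricsCohort <- function(spec, parc = defaultParcellation()) {
  gt <- sampleGroundTruth(spec, parc)
  n <- spec@nSubjects
  labels <- networkLabels()
  nets <- analysisNetworks()
  sizes <- table(factor(parc$network, levels = labels))
  set.seed(seedFor(spec@seed, 0L, 7L))
  meanFd <- gt@meanFdExpected * exp(0.1 * rnorm(n))
  fdz <- standardize(meanFd)

  wObs <- gt@withinZ + matrix(rnorm(n * length(labels), 0, spec@measurementSdW),
                              n, length(labels))
  colnames(wObs) <- labels
  bObs <- gt@betweenPairZ
  for (i in seq_len(n)) {
    noise <- matrix(0, length(labels), length(labels))
    noise[upper.tri(noise)] <- rnorm(sum(upper.tri(noise)), 0,
                                     spec@measurementSdB)
    noise <- noise + t(noise)
    bObs[, , i] <- bObs[, , i] + noise + spec@fdBetaBetween * fdz[i]
  }
  b13 <- sapply(nets, function(k) {
    others <- setdiff(labels, k)
    wts <- as.numeric(sizes[others])
    apply(bObs[k, others, , drop = FALSE], 3, function(v) sum(v * wts) / sum(wts))
  })
  b13 <- matrix(b13, n, length(nets), dimnames = list(NULL, nets))
  w13 <- wObs[, nets, drop = FALSE]
  seg <- (w13 - b13) / w13

  success <- vapply(seq_len(n), function(i) {
    tt <- simulateBehavior(spec, gt@trueSuccess[i], seedFor(spec@seed, i, 0L))
    rec <- reappraisalSuccess(cbind(subject_id = "s", tt))
    rec$success
  }, 0)

  pairsObs <- bObs[nets, nets, , drop = FALSE]
  list(gt = gt, age = gt@ages, meanFd = meanFd, success = success,
       successTrue = gt@trueSuccess, seg = seg, within = w13, between = b13,
       betweenPairs = pairsObs)
}

#' Write a full synthetic study to disk
#'
#' Generates and writes: the parcellation TSV, per-subject time-series TSVs
#' and realignment traces, the behavior CSV, a covariates CSV, the
#' ground-truth JSON, and a manifest with the seed and a hash of the
#' serialized spec. Byte-identical on re-run with the same spec.
#'
#' @param spec a [CohortSpec-class].
#' @param dir output directory (created if missing).
#' @param parc parcellation data.frame.
#' @return invisibly, the [GroundTruth-class].
#' @export
generateCohort <- function(spec, dir, parc = defaultParcellation()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- sampleGroundTruth(spec, parc)
  writeParcellation(parc, file.path(dir, "parcellation.tsv"))
  n <- spec@nSubjects
  ids <- sprintf("sub-%03d", seq_len(n))
  behav <- vector("list", n)
  for (i in seq_len(n)) {
    sdir <- file.path(dir, ids[i])
    dir.create(sdir, showWarnings = FALSE)
    sseed <- seedFor(spec@seed, i, 0L)
    motion <- simulateMotion(spec, sseed, gt@spikeRate[i])
    runs <- simulateRoiTimeseries(spec, parc, gt@withinZ[i, ],
                                  gt@betweenPairZ[, , i], sseed, motion)
    for (r in seq_along(runs)) {
      ts <- round(signalMatrix(runs[[r]]), 5)
      data.table::fwrite(as.data.frame(ts),
                         file.path(sdir, sprintf("run-%02d_timeseries.tsv", r)),
                         sep = "\t")
      mf <- file.path(sdir, sprintf("run-%02d_motion.txt", r))
      writeLines("# columns: rot_x rot_y rot_z (rad) trans_x trans_y trans_z (mm)", mf)
      data.table::fwrite(as.data.frame(round(motion[[r]]$trace, 6)), mf,
                         sep = " ", col.names = FALSE, append = TRUE)
    }
    tt <- simulateBehavior(spec, gt@trueSuccess[i], sseed)
    behav[[i]] <- cbind(subject_id = ids[i], tt)
  }
  data.table::fwrite(do.call(rbind, behav), file.path(dir, "behavior.csv"))
  data.table::fwrite(data.frame(subject_id = ids, age = round(gt@ages, 2),
                                sex = gt@sex),
                     file.path(dir, "covariates.csv"))
  jsonlite::write_json(
    list(seed = spec@seed,
         planted = gt@planted,
         subjects = ids,
         trueSegregation = as.data.frame(round(gt@trueSegregation, 6)),
         trueSuccess = round(gt@trueSuccess, 6)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  specPath <- file.path(dir, "spec.json")
  jsonlite::write_json(specAsList(spec), specPath, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = spec@seed, nSubjects = n,
         specHash = unname(tools::md5sum(specPath)),
         package = as.character(utils::packageVersion("netsegfc"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(gt)
}

specAsList <- function(spec) {
  nms <- slotNames("CohortSpec")
  out <- lapply(nms, function(nm) {
    v <- slot(spec, nm)
    if (length(names(v))) as.list(v) else v
  })
  names(out) <- nms
  out
}

#' Load a generated cohort
#'
#' @param dir directory written by [generateCohort()].
#' @return list with `parc`, `covariates`, `behavior`, `groundTruth`,
#'   `manifest`, `subjects`, and `dir`.
#' @export
loadCohort <- function(dir) {
  parc <- readParcellation(file.path(dir, "parcellation.tsv"))
  cov <- as.data.frame(data.table::fread(file.path(dir, "covariates.csv")))
  behav <- as.data.frame(data.table::fread(file.path(dir, "behavior.csv")))
  gtruth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(parc = parc, covariates = cov, behavior = behav, groundTruth = gtruth,
       manifest = manifest, subjects = cov$subject_id, dir = dir)
}

#' Read one subject's runs and motion traces
#'
#' @param dir cohort directory. @param subject subject id (e.g. "sub-001").
#' @param tr repetition time (s).
#' @return list with `runs` (list of [RoiRun-class]) and `motion`
#'   (list of frames x 6 matrices).
#' @export
readSubjectRuns <- function(dir, subject, tr) {
  sdir <- file.path(dir, subject)
  tsFiles <- sort(list.files(sdir, pattern = "timeseries\\.tsv$",
                             full.names = TRUE))
  moFiles <- sort(list.files(sdir, pattern = "motion\\.txt$",
                             full.names = TRUE))
  if (!length(tsFiles)) stop("no runs found for ", subject)
  runs <- lapply(tsFiles, function(f)
    new("RoiRun", signal = as.matrix(data.table::fread(f, sep = "\t")), tr = tr))
  motion <- lapply(moFiles, function(f)
    as.matrix(data.table::fread(f, skip = 1)))
  list(runs = runs, motion = motion)
}
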