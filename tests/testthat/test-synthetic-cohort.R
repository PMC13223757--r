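test_that("age sampling respects range, size, and seed", {
  spec <- cohortSpec(nSubjects = 227, seed = 4)
  ages <- sampleAges(spec)
  expect_length(ages, 227)
  expect_true(all(ages >= 6 & ages <= 80))
  expect_identical(ages, sampleAges(spec))
  expect_false(identical(ages, sampleAges(cohortSpec(nSubjects = 227,
                                                     seed = 5))))
  one <- cohortSpec(nSubjects = 1, ageRange = c(30, 30), seed = 1)
  expect_equal(sampleAges(one), 30)
  expect_error(cohortSpec(nSubjects = 0), "empty")
  expect_error(cohortSpec(ageRange = c(2, 90)), "ageRange")
})

test_that("spec invariants are enforced at construction", {
  expect_error(cohortSpec(withinZ = 0.1, betweenZ = 0.2), "exceed")
  expect_error(cohortSpec(nFramesPerRun = 700, nRuns = 1,
                          motionSpikeRate = 0), "frame budget")
  expect_error(cohortSpec(plantedBetaBetweenPair = c(SMdSMl = 0.2)),
               "pair effect")
  # a covariance target that is not positive definite is rejected
  spec <- cohortSpec(nSubjects = 1, seed = 1)
  parc <- smallParc()
  wz <- setNames(rep(0.15, 14), networkLabels())
  bz <- matrix(0.05, 14, 14, dimnames = list(networkLabels(), networkLabels()))
  bz["DMN", "DAN"] <- bz["DAN", "DMN"] <- 0.99  # cross > within: invalid
  expect_error(simulateRoiTimeseries(spec, parc, wz, bz, 1),
               "positive definite")
})

test_that("simulated runs realize the planted block correlations", {
  spec <- cohortSpec(nSubjects = 1, nFramesPerRun = 1000, seed = 8,
                     subjectSdWithin = 0, subjectSdBetween = 0,
                     subjectSdBetweenPair = 0, motionSpikeRate = 0,
                     globalAmp = 0, driftAmp = 0)
  parc <- defaultParcellation()
  gt <- sampleGroundTruth(spec, parc)
  runs <- simulateRoiTimeseries(spec, parc, gt@withinZ[1, ],
                                gt@betweenPairZ[, , 1], 123)
  r <- cor(signalMatrix(runs[[1]]))
  same <- outer(parc$network, parc$network, "==")
  up <- upper.tri(r)
  expect_equal(mean(r[same & up]), tanh(0.5), tolerance = 0.05)
  expect_equal(mean(r[!same & up]), tanh(0.1), tolerance = 0.05)
  # identical under the same seed
  runs2 <- simulateRoiTimeseries(spec, parc, gt@withinZ[1, ],
                                 gt@betweenPairZ[, , 1], 123)
  expect_identical(signalMatrix(runs[[1]]), signalMatrix(runs2[[1]]))
})

test_that("between = within forces segregation to zero", {
  parc <- smallParc()
  wz <- setNames(rep(0.3, 14), networkLabels())
  bz <- matrix(0.3, 14, 14, dimnames = list(networkLabels(), networkLabels()))
  spec <- cohortSpec(nSubjects = 1, nFramesPerRun = 900, seed = 2,
                     motionSpikeRate = 0, globalAmp = 0, driftAmp = 0)
  runs <- simulateRoiTimeseries(spec, parc, wz, bz, 9)
  plan <- selectFirstN(list(rep(TRUE, 900)), 800)
  cm <- thresholdNegatives(fisherZ(correlationMatrix(runs, plan)))
  s <- segregationValues(networkMetrics(cm, parc))
  expect_lt(max(abs(s)), 0.08)
})

test_that("planted structure holds per network across replicate subjects", {
  spec <- cohortSpec(nSubjects = 1, nFramesPerRun = 800, seed = 3,
                     subjectSdWithin = 0, subjectSdBetween = 0,
                     subjectSdBetweenPair = 0, motionSpikeRate = 0,
                     globalAmp = 0, driftAmp = 0)
  parc <- defaultParcellation()
  gt <- sampleGroundTruth(spec, parc)
  nets <- analysisNetworks()
  ok <- 0L; total <- 0L
  for (repl in 1:100) {
    runs <- simulateRoiTimeseries(spec, parc, gt@withinZ[1, ],
                                  gt@betweenPairZ[, , 1], 5000 + repl)
    r <- cor(signalMatrix(runs[[1]]))
    up <- upper.tri(r)
    for (k in nets) {
      ik <- parc$network == k
      wOk <- abs(mean(r[ik, ik][upper.tri(r[ik, ik])]) - tanh(0.5)) <= 0.05
      bOk <- abs(mean(r[ik, !ik]) - tanh(0.1)) <= 0.05
      ok <- ok + wOk + bOk
      total <- total + 2L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("motion traces have the declared structure", {
  spec <- cohortSpec(nSubjects = 1, seed = 6, motionSpikeRate = 0,
                     motionWalkSd = 0)
  m <- simulateMotion(spec, 11)
  expect_equal(dim(m[[1]]$trace), c(900, 6))
  fd <- fdValues(computeFd(m[[1]]$trace, tr = 1))
  expect_equal(fd, rep(0, 900))  # no spikes, no walk -> flat

  spec2 <- cohortSpec(nSubjects = 1, seed = 6, nFramesPerRun = 1200)
  m2 <- simulateMotion(spec2, 11, spikeRate = 0.05)
  expect_identical(m2, simulateMotion(spec2, 11, spikeRate = 0.05))
  expect_false(identical(m2, simulateMotion(spec2, 12, spikeRate = 0.05)))
})

test_that("censored fraction matches the spike-model expectation", {
  spec <- cohortSpec(nSubjects = 1, seed = 66, nFramesPerRun = 1000,
                     motionWalkSd = 0)
  rate <- 0.05
  # filtered response of one isolated spike characterizes the spike model
  single <- matrix(0, 200, 6); single[100, 4] <- spec@motionSpikeScale
  h <- fdValues(filterFd(computeFd(single, tr = 1)))
  expect_gt(sum(h > 0.2), 0)  # a spike really censors frames
  h <- h[h > 1e-4]
  # expectation under the spike model: Bernoulli spike train pushed through
  # the linear filter response, thresholded (superposition included)
  set.seed(1)
  expected <- mean(replicate(400, {
    train <- rbinom(1000, 1, rate)
    fdModel <- as.numeric(stats::filter(c(train, numeric(length(h))),
                                        h, sides = 1))[seq_len(1000)]
    fdModel[is.na(fdModel)] <- 0
    mean(fdModel > 0.2)
  }))
  fracs <- vapply(1:20, function(i) {
    m <- simulateMotion(spec, 800 + i, spikeRate = rate)
    mean(!censorFrames(filterFd(computeFd(m[[1]]$trace, tr = 1))))
  }, 0)
  expect_lt(abs(mean(fracs) - expected), 0.03)
})

test_that("behavior generator honors the noise-free contract", {
  spec <- cohortSpec(nSubjects = 5, seed = 7, ratingNoiseSd = 0,
                     lookNegBaseline = 3.5)
  tt <- simulateBehavior(spec, trueSuccess = 1.0, subjectSeed = 42)
  expect_equal(nrow(tt), 60)
  expect_equal(unname(table(tt$condition)["Decrease"]), 20L)
  expect_true(all(tt$rating %in% 1:5))
  rec <- reappraisalSuccess(cbind(subject_id = "s", tt))
  expect_equal(rec$success, 1.0)

  noisy <- simulateBehavior(cohortSpec(nSubjects = 5, seed = 7), 1.0, 42)
  expect_true(all(noisy$rating >= 1 & noisy$rating <= 5))
  expect_identical(simulateBehavior(spec, 1.0, 42), tt)
})

test_that("with no planted effects and no noise, success depends on age only", {
  empty <- setNames(numeric(0), character(0))
  spec <- cohortSpec(nSubjects = 60, seed = 13, plantedBetaSeg = empty,
                     noiseSd = 0, ratingNoiseSd = 0)
  gt <- sampleGroundTruth(spec)
  zAge <- standardize(gt@ages)
  pred <- 1.02 + 0.75 * (-0.25) * (zAge^2 - mean(zAge^2))
  expect_equal(gt@trueSuccess, pred, tolerance = 1e-12)
})

test_that("ground truth and metric cohort are seed-deterministic", {
  spec <- cohortSpec(nSubjects = 30, seed = 17)
  a <- simulateMetricsCohort(spec)
  b <- simulateMetricsCohort(spec)
  expect_identical(a$seg, b$seg)
  expect_identical(a$success, b$success)
  expect_identical(a$gt@trueSuccess, b$gt@trueSuccess)
  c <- simulateMetricsCohort(cohortSpec(nSubjects = 30, seed = 18))
  expect_false(identical(a$seg, c$seg))
})

test_that("cohort generation writes a complete, reproducible dataset", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  parc <- smallParc()
  spec <- cohortSpec(nSubjects = 3, nFramesPerRun = 850, seed = 23,
                     motionSpikeRate = 0.01)
  gt <- generateCohort(spec, dir1, parc)
  expect_true(file.exists(file.path(dir1, "parcellation.tsv")))
  expect_true(file.exists(file.path(dir1, "behavior.csv")))
  expect_true(file.exists(file.path(dir1, "ground_truth.json")))
  subs <- sprintf("sub-%03d", 1:3)
  expect_true(all(dir.exists(file.path(dir1, subs))))

  cohort <- loadCohort(dir1)
  expect_equal(cohort$subjects, subs)
  expect_equal(cohort$manifest$nSubjects, 3)
  expect_equal(nrow(cohort$behavior), 3 * 60)
  # planted coefficients serialized: 0.35 for DMN, nothing else
  expect_equal(cohort$groundTruth$planted$betaSeg$DMN, 0.35)
  expect_length(cohort$groundTruth$planted$betaSeg, 1)

  generateCohort(spec, dir2, parc)
  f1 <- file.path(dir1, subs[1], "run-01_timeseries.tsv")
  f2 <- file.path(dir2, subs[1], "run-01_timeseries.tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(dir1, "behavior.csv")),
                   readLines(file.path(dir2, "behavior.csv")))

  sub <- readSubjectRuns(dir1, subs[1], tr = 1)
  expect_length(sub$runs, 1)
  expect_equal(nFrames(sub$runs[[1]]), 850)
  expect_equal(nRois(sub$runs[[1]]), nrow(parc))
  expect_equal(dim(sub$motion[[1]]), c(850, 6))
})
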