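test_that("correlation matrix matches a brute-force pairwise loop", {
  set.seed(3)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  run <- makeRun(X)
  plan <- selectFirstN(list(rep(TRUE, n)), n)
  r <- correlationMatrix(list(run), plan)
  ref <- matrix(1, p, p)
  for (a in 1:p) for (b in 1:p)
    ref[a, b] <- sum((X[, a] - mean(X[, a])) * (X[, b] - mean(X[, b]))) /
      sqrt(sum((X[, a] - mean(X[, a]))^2) * sum((X[, b] - mean(X[, b]))^2))
  dimnames(ref) <- dimnames(r)
  expect_equal(r, ref, tolerance = 1e-12)

  # duplicated ROI -> r = 1
  X2 <- cbind(X, X[, 1])
  r2 <- correlationMatrix(list(makeRun(X2)), plan)
  expect_equal(unname(r2[1, p + 1]), 1)

  # zero-variance ROI errors, naming the ROI
  X3 <- X; X3[, 2] <- 5
  colnames(X3) <- paste0("R", 1:p)
  expect_error(correlationMatrix(list(makeRun(X3)), plan), "R2")
})

test_that("only selected frames enter the correlation", {
  set.seed(4)
  X <- matrix(rnorm(900 * 3), 900, 3)
  X[801:900, ] <- 1e3 * matrix(rnorm(100 * 3), 100, 3)  # junk in the tail
  plan <- selectFirstN(list(rep(TRUE, 900)), 800)
  r <- correlationMatrix(list(makeRun(X)), plan)
  expect_equal(r, cor(X[1:800, ]), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("white-noise correlations concentrate near zero at n = 800", {
  set.seed(5)
  r <- correlationMatrix(list(makeRun(matrix(rnorm(800 * 40), 800, 40))),
                         selectFirstN(list(rep(TRUE, 800)), 800))
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 0.1), 0.99)
})

test_that("Fisher z-transform is atanh off the diagonal", {
  r <- matrix(c(1, 0, 0.462, 0, 1, -0.3, 0.462, -0.3, 1), 3, 3)
  cm <- fisherZ(r)
  z <- zMatrix(cm)
  expect_equal(unname(z[1, 2]), 0)
  expect_equal(unname(z[1, 3]), atanh(0.462), tolerance = 1e-12)
  expect_equal(unname(z[1, 3]), 0.5, tolerance = 1e-3)
  expect_equal(unname(z[2, 3]), atanh(-0.3))   # sign preserved pre-threshold
  expect_true(all(is.na(diag(z))))
  bad <- r; bad[1, 2] <- bad[2, 1] <- 1
  expect_error(fisherZ(bad), "< 1")
})

test_that("negative thresholding zeroes exactly the negative entries", {
  z <- randomZMatrix(15, seed = 8)
  cm <- new("ConnectivityMatrix", z = z, thresholded = FALSE)
  th <- zMatrix(thresholdNegatives(cm))
  nNegBrute <- 0
  for (a in 1:15) for (b in 1:15) if (a != b && z[a, b] < 0)
    nNegBrute <- nNegBrute + 1
  expect_equal(sum(th == 0, na.rm = TRUE) - sum(z == 0, na.rm = TRUE),
               nNegBrute)
  expect_equal(th[!is.na(z) & z >= 0], z[!is.na(z) & z >= 0])
  expect_true(all(th[!is.na(th)] >= 0))

  allPos <- abs(z)
  cmp <- thresholdNegatives(new("ConnectivityMatrix", z = allPos,
                                thresholded = FALSE))
  expect_equal(zMatrix(cmp), allPos)
  allNeg <- -abs(z)
  cmn <- thresholdNegatives(new("ConnectivityMatrix", z = allNeg,
                                thresholded = FALSE))
  expect_true(all(zMatrix(cmn)[!is.na(allNeg)] == 0))
})

test_that("within/between means reproduce a constant-block hand example", {
  parc <- toyParc(3, 3)
  z <- matrix(0.2, 6, 6)
  z[1:3, 1:3] <- 0.6
  z[4:6, 4:6] <- 0.6
  diag(z) <- NA_real_
  cm <- new("ConnectivityMatrix", z = z, thresholded = TRUE)
  met <- networkMetrics(cm, parc)
  expect_equal(unname(withinConnectivity(met)), c(0.6, 0.6))
  expect_equal(unname(betweenConnectivity(met)), c(0.2, 0.2))
  expect_equal(unname(betweenPairs(met)["DMN", "DAN"]), 0.2)
  expect_equal(unname(segregationValues(met)),
               rep((0.6 - 0.2) / 0.6, 2), tolerance = 1e-12)
})

test_that("network metrics agree with a double-loop reference", {
  parc <- smallParc(roisPerNet = 2L, unassigned = 3L)  # 29 ROIs
  for (seed in 1:5) {
    z <- abs(randomZMatrix(nrow(parc), seed = seed))
    cm <- new("ConnectivityMatrix", z = z, thresholded = TRUE)
    for (mode in c("brainwide", "labeled")) {
      met <- networkMetrics(cm, parc, betweenMode = mode)
      ref <- oracleWithinBetween(z, parc, betweenMode = mode)
      expect_equal(withinConnectivity(met), ref$W, tolerance = 1e-12)
      expect_equal(betweenConnectivity(met), ref$B, tolerance = 1e-12)
      expect_equal(segregationValues(met), ref$S, tolerance = 1e-12)
    }
    met <- networkMetrics(cm, parc)
    expect_equal(betweenPairs(met)["DMN", "DAN"],
                 betweenPairs(met)["DAN", "DMN"])
  }
})

test_that("segregation index follows its formula and edge cases", {
  expect_equal(segregationIndex(0.6, 0.2), 0.4 / 0.6)
  expect_equal(round(segregationIndex(0.6, 0.2), 4), 0.6667)
  expect_equal(segregationIndex(0.5, 0.5), 0)
  expect_equal(segregationIndex(0.7, 0), 1)
  expect_warning(s <- segregationIndex(c(0.5, -0.1), c(0.1, 0.05)),
                 "undefined")
  expect_equal(s, c(0.8, NA))
})

test_that("segregation is invariant to positive rescaling", {
  parc <- smallParc(roisPerNet = 3L)
  z <- abs(randomZMatrix(nrow(parc), seed = 13))
  cm <- new("ConnectivityMatrix", z = z, thresholded = TRUE)
  s1 <- segregationValues(networkMetrics(cm, parc))
  cm2 <- new("ConnectivityMatrix", z = 3.7 * z, thresholded = TRUE)
  s2 <- segregationValues(networkMetrics(cm2, parc))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("shuffling network labels destroys planted segregation", {
  spec <- cohortSpec(nSubjects = 1, nFramesPerRun = 900, seed = 31,
                     subjectSdWithin = 0, subjectSdBetween = 0,
                     subjectSdBetweenPair = 0, motionSpikeRate = 0,
                     globalAmp = 0, driftAmp = 0)
  parc <- defaultParcellation()
  gt <- sampleGroundTruth(spec, parc)
  runs <- simulateRoiTimeseries(spec, parc, gt@withinZ[1, ],
                                gt@betweenPairZ[, , 1], 77)
  plan <- selectFirstN(list(rep(TRUE, 900)), 800)
  cm <- thresholdNegatives(fisherZ(correlationMatrix(runs, plan)))
  sPlanted <- mean(segregationValues(networkMetrics(cm, parc)))
  set.seed(1)
  shuffled <- parc
  shuffled$network <- sample(parc$network)
  sShuffled <- mean(segregationValues(networkMetrics(cm, shuffled)))
  expect_gt(sPlanted, 0.7)
  expect_lt(abs(sShuffled), 0.1)
})

test_that("connectivity CSV round-trips", {
  z <- abs(randomZMatrix(10, seed = 2))
  rownames(z) <- colnames(z) <- sprintf("ROI%03d", 1:10)
  cm <- new("ConnectivityMatrix", z = z, thresholded = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeConnectivityCsv(cm, path)
  back <- readConnectivityCsv(path, thresholded = TRUE)
  expect_equal(zMatrix(back), z, tolerance = 1e-12)
})
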