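test_that("FD residualization is exact and orthogonal", {
  set.seed(9)
  fd <- abs(rnorm(80, 0.1, 0.03))
  x <- rnorm(80)
  r <- residualizeOnFd(x, fd)
  expect_lt(abs(sum(r * fd)), 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  expect_lt(max(abs(residualizeOnFd(2 * fd, fd))), 1e-10)
  expect_error(residualizeOnFd(1:3, 1:2), "mismatch")
})

test_that("residualization removes the generator's motion confound", {
  mc <- simulateMetricsCohort(cohortSpec(nSubjects = 227, seed = 303))
  raw <- cor(mc$seg[, "DMN"], mc$meanFd)
  expect_lt(raw, -0.15)  # the confound is really there
  res <- residualizeOnFd(mc$seg[, "DMN"], mc$meanFd)
  expect_lt(abs(cor(res, mc$meanFd)), 0.01)
})

test_that("OLS agrees with the normal-equations oracle", {
  # 5-point hand example
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(0, 1, 0, 1, 0))
  fit <- fitLinearModel(y, X)
  ref <- oracleOls(y, X)
  expect_equal(fit@coefficients$B, ref$beta, tolerance = 1e-10)
  expect_equal(fit@coefficients$SE, ref$se, tolerance = 1e-10)
  # random designs, checked against lm() and stats::AIC as well
  set.seed(10)
  for (i in 1:8) {
    n <- sample(15:40, 1); p <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("v", 1:p)))
    yr <- rnorm(n)
    fr <- fitLinearModel(yr, Xr)
    rr <- oracleOls(yr, Xr)
    expect_equal(fr@coefficients$B, rr$beta, tolerance = 1e-10)
    lmfit <- lm(yr ~ Xr)
    expect_equal(fr@aic, stats::AIC(lmfit), tolerance = 1e-8)
    expect_equal(fr@r2, summary(lmfit)$r.squared, tolerance = 1e-10)
    expect_equal(fr@pOverall,
                 unname(pf(summary(lmfit)$fstatistic[1],
                           summary(lmfit)$fstatistic[2],
                           summary(lmfit)$fstatistic[3], lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
})

test_that("exact linear data give R2 = 1 and rank deficiency errors", {
  X <- cbind(a = 1:20, b = rep(c(1, 2), 10))
  y <- 2 + 3 * X[, "a"] - X[, "b"]
  fit <- fitLinearModel(y, X)
  expect_equal(fit@r2, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit@coefficients$B - c(2, 3, -1))), 1e-10)
  expect_error(fitLinearModel(y, cbind(a = 1:20, b = 2 * (1:20))),
               "rank-deficient")
})

test_that("permutation destroys a planted effect (null p is uniform)", {
  set.seed(12)
  n <- 40
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  pPerm <- replicate(400, {
    f <- fitLinearModel(sample(y), cbind(x = x))
    f@coefficients$p[2]
  })
  expect_lt(abs(mean(pPerm < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(pPerm) - 0.5), 0.05)
  expect_lt(fitLinearModel(y, cbind(x = x))@coefficients$p[2], 1e-4)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("per-network segregation models report coefficients with FDR", {
  mc <- simulateMetricsCohort(cohortSpec(nSubjects = 227, seed = 77))
  sz <- standardize(mc$success); az <- standardize(mc$age)
  segR <- apply(mc$seg, 2, residualizeOnFd, meanFd = mc$meanFd)
  res <- segregationModels(sz, segR, az)
  expect_equal(nrow(res$summary), 13)
  expect_setequal(res$summary$network, analysisNetworks())
  expect_equal(res$summary$pModelFdr,
               oracleBH(res$summary$pModel), tolerance = 1e-12)
  f <- res$fits$DMN
  expect_equal(f@coefficients$term,
               c("(Intercept)", "Segregation", "AgeLinear", "AgeQuadratic"))
  expect_equal(f@df2, f@n - 4L)
  # the planted DMN effect is the strongest segregation signal
  expect_equal(res$summary$network[which.min(res$summary$pSegFdr)], "DMN")
  # the planted quadratic age effect shows up in every model
  qp <- vapply(res$fits, function(f)
    f@coefficients$p[f@coefficients$term == "AgeQuadratic"], 0)
  expect_true(all(qp < 0.01))
})

test_that("within/between models recover planted signs", {
  empty <- setNames(numeric(0), character(0))
  # success driven by +within DMN only
  mcW <- simulateMetricsCohort(cohortSpec(
    nSubjects = 227, seed = 21, plantedBetaSeg = empty,
    plantedBetaWithin = c(DMN = 0.4)))
  fitOne <- function(mc) {
    sz <- standardize(mc$success); az <- standardize(mc$age)
    wR <- apply(mc$within, 2, residualizeOnFd, meanFd = mc$meanFd)
    bR <- apply(mc$between, 2, residualizeOnFd, meanFd = mc$meanFd)
    withinBetweenModels(sz, wR, bR, az)
  }
  co <- function(f, term) f@coefficients[f@coefficients$term == term, ]
  fW <- fitOne(mcW)$DMN
  expect_lt(co(fW, "Within")$p, 0.01)
  expect_gt(co(fW, "Within")$B, 0)
  expect_gt(co(fW, "Between")$p, 0.01)
  expect_gt(co(fW, "Between:Age")$p, 0.01)  # no planted moderation

  # SMd-style structure: -within, +between (via the SMl pair)
  mcS <- simulateMetricsCohort(cohortSpec(
    nSubjects = 227, seed = 22, plantedBetaSeg = empty,
    plantedBetaWithin = c(SMd = -0.35),
    plantedBetaBetweenPair = c("SMd-SMl" = 0.3)))
  fS <- fitOne(mcS)$SMd
  expect_lt(co(fS, "Within")$B, 0)
  expect_lt(co(fS, "Within")$p, 0.05)
  expect_gt(co(fS, "Between")$B, 0)

  # quadratic-age interactions are opt-in
  sz <- standardize(mcS$success); az <- standardize(mcS$age)
  wR <- apply(mcS$within, 2, residualizeOnFd, meanFd = mcS$meanFd)
  bR <- apply(mcS$between, 2, residualizeOnFd, meanFd = mcS$meanFd)
  f8 <- withinBetweenModels(sz, wR, bR, az, quadraticInteractions = TRUE)$SMd
  expect_equal(nrow(f8@coefficients), 9)
})

test_that("network contrast t-test matches the textbook formula", {
  parc <- toyParc(3, 2)
  betas <- matrix(0, 5, 5, dimnames = list(NULL, parc$roi_id))
  out0 <- networkContrastTtest(betas, parc, networks = c("DMN", "DAN"))
  expect_equal(out0$t, c(0, 0))

  set.seed(15)
  betas <- matrix(rnorm(25, 0.3), 5, 5, dimnames = list(NULL, parc$roi_id))
  out <- networkContrastTtest(betas, parc, networks = "DMN")
  v <- rowMeans(betas[, 1:3])
  tRef <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(out$t, tRef, tolerance = 1e-10)
  expect_equal(out$df, 4)

  # df follows the chosen axis, not the other dimension
  big <- matrix(rnorm(227 * 5), 227, 5, dimnames = list(NULL, parc$roi_id))
  bySubj <- networkContrastTtest(big, parc, networks = "DMN")
  expect_equal(bySubj$df, 226)
  byRoi <- networkContrastTtest(big, parc, networks = "DMN", axis = "rois")
  expect_equal(byRoi$df, 2)  # 3 DMN ROIs - 1
})
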