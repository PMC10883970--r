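test_that("Cochran Q matches a term-by-term oracle and its identities", {
  ## identical ratios: Q = 0, p = 1
  h0 <- makeH(c(1, 2, 4), c(0.3, 0.6, 1.2), seO = 0.01)
  q0 <- cochranQ(h0)
  expect_equal(q0$Q, 0, tolerance = 1e-18)
  expect_equal(q0$p, 1)
  ## df = n - 1 (22 instruments -> 21)
  h22 <- simStudy(13, palindromicFrac = 0)$h
  expect_equal(cochranQ(h22)$df, 21)
  ## summation oracle on a 10-IV fixture
  set.seed(14)
  h10 <- makeH(runif(10, 0.05, 0.2), rnorm(10, 0, 0.05),
               seO = runif(10, 0.01, 0.05))
  wr <- waldRatios(h10)
  bIvw <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  qOracle <- 0
  for (j in 1:10) qOracle <- qOracle + wr$weight[j] * (wr$ratio[j] - bIvw)^2
  q10 <- cochranQ(h10)
  expect_equal(q10$Q, qOracle)
  ## Q equals the weighted RSS of the IVW fit (algebraic identity)
  g <- exposureBeta(h10)[, 1]
  rss <- sum((outcomeBeta(h10) - bIvw * g)^2 / outcomeSE(h10)^2)
  expect_equal(q10$Q, rss, tolerance = 1e-10)
})

test_that("MR-PRESSO is seed-deterministic, bounded, and flags a spiked IV", {
  h <- simStudy(15)$h
  a <- mrPresso(h, nSim = 300, seed = 7)
  b <- mrPresso(h, nSim = 300, seed = 7)
  expect_identical(a$globalP, b$globalP)
  expect_identical(a$perSnpP, b$perSnpP)
  expect_gte(a$globalP, 1 / 301)
  expect_lte(a$globalP, 1)
  ## clean data: global test quiet; under the raw per-SNP 0.05 rule a
  ## false flag or two among 22 instruments is expected behaviour
  expect_gt(a$globalP, 0.05)
  expect_lte(nrow(a$outliers), 3)
  expect_equal(snpTable(a$filtered)$snp,
               setdiff(snpTable(h)$snp, a$outliers$snp))

  ## displace one outcome beta by 10 sigma
  hS <- h
  spike <- 5
  hS@betaOutcome[spike] <- hS@betaOutcome[spike] + 10 * hS@seOutcome[spike]
  pr <- mrPresso(hS, nSim = 500, seed = 8)
  expect_lt(pr$globalP, 0.05)
  expect_true(snpTable(h)$snp[spike] %in% pr$outliers$snp)
  expect_lt(pr$outliers$p[pr$outliers$snp == snpTable(h)$snp[spike]], 0.05)
  ## filtered = input minus flagged, order preserved
  expect_equal(snpTable(pr$filtered)$snp,
               setdiff(snpTable(hS)$snp, pr$outliers$snp))
  expect_error(mrPresso(simStudy(1, nIV = 3)$h), ">= 4")
})

test_that("Steiger direction depends only on the summed r2 and flips with the traits", {
  ## construction: strong exposure effects, weak outcome effects
  h <- makeH(gamma = rep(0.1, 10), Gamma = rep(0.01, 10), seG = 0.005,
             seO = 0.005, nExposure = 5e5, nOutcome = 5e5)
  st <- steigerTest(h)
  expect_true(st$directionOk)
  expect_gt(st$r2Exposure, st$r2Outcome)
  ## swapping exposure and outcome flips the verdict
  hSwap <- makeH(gamma = rep(0.01, 10), Gamma = rep(0.1, 10), seG = 0.005,
                 seO = 0.005, nExposure = 5e5, nOutcome = 5e5)
  stSwap <- steigerTest(hSwap)
  expect_false(stSwap$directionOk)
  expect_equal(st$r2Exposure, stSwap$r2Outcome)
  ## equal explained variance: p near 1, direction not asserted
  hEq <- makeH(gamma = rep(0.05, 4), Gamma = rep(0.05, 4), seG = 0.01,
               seO = 0.01, nExposure = 1e5, nOutcome = 1e5)
  stEq <- steigerTest(hEq)
  expect_false(stEq$directionOk)
  expect_gt(stEq$p, 0.99)
  ## study-scale magnitudes: direction clearly correct
  h22 <- simStudy(16)$h
  s22 <- steigerTest(h22)
  expect_true(s22$directionOk)
  expect_lt(s22$p, 1e-10)
  expect_error(steigerTest(makeH(1, 1), nExposure = NA), "missing")
})

test_that("leave-one-out reproduces the full estimate structure", {
  ## all IVs identical: every reduced estimate equals the full one
  h0 <- makeH(rep(1, 5), rep(0.4, 5), seO = 0.05)
  loo0 <- leaveOneOut(h0)
  expect_true(all(abs(loo0$beta - 0.4) < 1e-12))
  ## 22 instruments -> 22 rows
  h22 <- simStudy(17, palindromicFrac = 0)$h
  loo <- leaveOneOut(h22)
  expect_equal(nrow(loo), 22)
  expect_true(isTRUE(attr(loo, "robust")))
  ## spiked fixture: removing the outlier moves the estimate most
  hS <- h22
  hS@betaOutcome[3] <- hS@betaOutcome[3] + 12 * hS@seOutcome[3]
  looS <- leaveOneOut(hS)
  full <- attr(looS, "full")@beta
  shift <- abs(looS$beta - full)
  expect_equal(which.max(shift), 3)
  ## and the outlier-free estimate is closest to the truth
  expect_equal(which.min(abs(looS$beta - (-0.6))), 3)
})

test_that("Egger intercept test recovers injected pleiotropy and stays calibrated", {
  set.seed(18)
  g <- runif(12, 0.05, 0.2)
  h <- makeH(g, 0.5 * g + 0.02, seO = 0.004)
  it <- eggerInterceptTest(h)
  expect_equal(it$intercept, 0.02, tolerance = 1e-10)
  expect_lt(it$p, 0.05)
  ## null calibration at roughly 5% (balanced pleiotropy, InSIDE holds)
  rej <- vapply(1:300, function(s) {
    sim <- simulateIvData(mrSimConfig(nIV = 15, propInvalid = 1,
                                      pleiotropyMode = "balanced",
                                      pleiotropySd = 0.002, seed = 1000 + s))
    eggerInterceptTest(harmonizePair(sim$exposure, sim$outcome))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("sensitivitySuite bundles consistent diagnostics", {
  h <- simStudy(19)$h
  rep <- sensitivitySuite(h, pressoNSim = 200, seed = 3)
  expect_s4_class(rep, "SensitivityReport")
  expect_equal(rep@qDf, nIV(h) - 1)
  expect_equal(nrow(rep@loo), nIV(h))
  expect_true(all(rep@pressoOutliers$snp %in% snpTable(h)$snp))
  expect_true(rep@steiger$directionOk)
})
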