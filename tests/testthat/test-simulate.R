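test_that("identical seeds give byte-identical simulated tables", {
  a <- simulateIvData(mrSimConfig(seed = 9))
  b <- simulateIvData(mrSimConfig(seed = 9))
  expect_identical(snpTable(a$exposure), snpTable(b$exposure))
  expect_identical(snpTable(a$outcome), snpTable(b$outcome))
  expect_identical(a$truth, b$truth)
  c <- simulateIvData(mrSimConfig(seed = 10))
  expect_false(identical(snpTable(c$outcome), snpTable(a$outcome)))

  g1 <- simulateGenomeScan(genomeSimConfig(mSnps = 2000, seed = 4))
  g2 <- simulateGenomeScan(genomeSimConfig(mSnps = 2000, seed = 4))
  expect_identical(g1, g2)
})

test_that("simulated moments match the generative parameters", {
  cfg <- mrSimConfig(nIV = 2000, trueBeta = -0.6, gammaMean = 0.01,
                     gammaSd = 0.0025, hetSd = 0.002, seed = 21)
  sim <- simulateIvData(cfg)
  g <- snpTable(sim$exposure)$beta
  G <- snpTable(sim$outcome)$beta
  n <- length(g)
  ## gammahat: mean gammaMean, var gammaSd^2 + 1/nExposure
  sdG <- sqrt(0.0025^2 + 1 / 446118)
  expect_lt(abs(mean(g) - 0.01), 4 * sdG / sqrt(n))
  expect_lt(abs(sd(g) - sdG), 4 * sdG / sqrt(2 * n))
  ## Gammahat: mean trueBeta*gammaMean, var = beta^2 gammaSd^2 + hetSd^2 + 1/nOutcome
  sdO <- sqrt(0.6^2 * 0.0025^2 + 0.002^2 + 1 / 1012240)
  expect_lt(abs(mean(G) - (-0.6 * 0.01)), 4 * sdO / sqrt(n))
  expect_lt(abs(sd(G) - sdO), 4 * sdO / sqrt(2 * n))
  ## ground truth is a sidecar, never part of the sumstats tables
  expect_false("gamma" %in% names(snpTable(sim$exposure)))
  expect_true(all(c("gamma", "alpha", "invalid") %in% names(sim$truth)))
})

test_that("null model is calibrated: IVW rejects at roughly the nominal rate", {
  reject <- vapply(1:1000, function(s) {
    h <- simStudy(s, trueBeta = 0, nIV = 10)$h
    mrIvw(h, "fixed")@pvalue < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("invalid-IV bookkeeping and pleiotropy modes behave as configured", {
  sim <- simulateIvData(mrSimConfig(nIV = 100, propInvalid = 0.4,
                                    pleiotropyMode = "directional",
                                    pleiotropyMean = 0.05,
                                    pleiotropySd = 0.001, seed = 2))
  expect_equal(sum(sim$truth$invalid), 40)
  expect_true(all(sim$truth$alpha[!sim$truth$invalid] == 0))
  expect_gt(mean(sim$truth$alpha[sim$truth$invalid]), 0.04)
  ## correlated mode violates InSIDE: corr(alpha, gamma) near 0.5
  sim2 <- simulateIvData(mrSimConfig(nIV = 2000, propInvalid = 1,
                                     pleiotropyMode = "correlated",
                                     pleiotropySd = 0.01, seed = 3))
  expect_gt(cor(sim2$truth$alpha, sim2$truth$gamma), 0.3)
  expect_lt(cor(sim2$truth$alpha, sim2$truth$gamma), 0.7)
  expect_error(simulateIvData(mrSimConfig(trueBeta = Inf)), "finite")
})

test_that("genome scan reproduces the LD-score expectation", {
  cfg <- genomeSimConfig(mSnps = 20000, rg = 1, h2_1 = 0.3, h2_2 = 0.3,
                         seed = 5)
  gs <- simulateGenomeScan(cfg)
  ## rg = 1 with equal h2 and n: z-scores correlated up to per-cohort
  ## sampling noise, and the regression recovers rg = 1 within jackknife SE
  expect_gt(cor(gs$z1$z, gs$z2$z), 0.5)
  r1 <- ldscRg(gs$z1, gs$z2)
  expect_lt(abs(r1@rg - 1), 2.5 * r1@rgSE)
  ## ld scores: 1 + (block size - 1) * r_b^2, block-constant and >= 1
  expect_true(all(gs$z1$ldscore >= 1))
  expect_identical(gs$z1$ldscore, gs$z2$ldscore)
  ## rg = 0: cross products regress to a flat line
  gs0 <- simulateGenomeScan(genomeSimConfig(mSnps = 20000, rg = 0, seed = 6))
  r0 <- ldscRg(gs0$z1, gs0$z2)
  expect_lt(abs(r0@rg), 2 * r0@rgSE)
  expect_error(simulateGenomeScan(new("GenomeSimConfig", mSnps = 10L,
                                      n1 = 100, n2 = 100, h2_1 = 0.1,
                                      h2_2 = 0.1, rg = 1.5, blockSize = 5L,
                                      withinBlockR = 0.5, seed = 1L)))
})

test_that("block LD reference reports r2 by construction", {
  ld <- simulateLdReference(nSnps = 10, blockSize = 5, r = 0.9)
  info <- ldSnpInfo(ld)
  expect_equal(ldR2(ld, info$snp[1], info$snp[1]), 1)
  ## all 10 within-block pairs at r^2 = 0.81
  for (pair in combn(1:5, 2, simplify = FALSE))
    expect_equal(ldR2(ld, info$snp[pair[1]], info$snp[pair[2]]), 0.81)
  ## across blocks: 0
  expect_equal(ldR2(ld, info$snp[1], info$snp[6]), 0)
  ## symmetry
  expect_equal(ldR2(ld, info$snp[2], info$snp[4]),
               ldR2(ld, info$snp[4], info$snp[2]))
})
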