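test_that("Wald ratios are element-wise division with first-order SEs", {
  h <- makeH(gamma = 1, Gamma = 0.5, seO = 0.1)
  wr <- waldRatios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(waldRatios(makeH(gamma = -2, Gamma = 1))$ratio, -0.5)
  ## vectorized against scalar loop
  set.seed(1)
  g <- rnorm(5, 0.1, 0.02); G <- rnorm(5); seO <- runif(5, 0.01, 0.1)
  h5 <- makeH(g, G, seO = seO)
  wr5 <- waldRatios(h5)
  for (j in 1:5) {
    expect_equal(wr5$ratio[j], G[j] / g[j])
    expect_equal(wr5$se[j], seO[j] / abs(g[j]))
    expect_equal(wr5$weight[j], g[j]^2 / seO[j]^2)
  }
  expect_error(waldRatios(makeH(c(0.1, 0), c(1, 1))), "iv_2")
})

test_that("IVW equals weighted least squares through the origin", {
  for (seed in 1:5) {
    h <- simStudy(seed)$h
    oracle <- ivwWlsOracle(h)
    est <- mrIvw(h, "fixed")
    expect_equal(est@beta, oracle$beta, tolerance = 1e-10)
    expect_equal(est@se, oracle$se, tolerance = 1e-10)
  }
  ## single IV degenerates to the Wald ratio
  h1 <- makeH(gamma = 0.5, Gamma = 0.2, seO = 0.05)
  e1 <- mrIvw(h1, "fixed")
  expect_equal(e1@beta, 0.4)
  expect_equal(e1@se, 0.05 / 0.5)
  ## identical ratios: Q = 0, fixed = random SE
  h2 <- makeH(gamma = c(1, 2, 4), Gamma = c(0.3, 0.6, 1.2), seO = 0.01)
  ef <- mrIvw(h2, "fixed"); er <- mrIvw(h2, "random")
  expect_equal(ef@beta, 0.3)
  expect_equal(ef@extra$Q, 0, tolerance = 1e-20)
  expect_equal(ef@se, er@se)
})

test_that("Egger recovers slope and intercept on noiseless fixtures", {
  set.seed(2)
  g <- runif(10, 0.05, 0.2)
  ## exact model, no pleiotropy: slope beta, intercept 0
  h <- makeH(g, 0.7 * g, seO = 0.05)
  e <- mrEgger(h)
  expect_equal(e@beta, 0.7, tolerance = 1e-10)
  expect_equal(e@extra$intercept, 0, tolerance = 1e-10)
  ## constant directional pleiotropy alpha shifts only the intercept
  h2 <- makeH(g, 0.7 * g + 0.03, seO = 0.05)
  e2 <- mrEgger(h2)
  expect_equal(e2@beta, 0.7, tolerance = 1e-10)
  expect_equal(e2@extra$intercept, 0.03, tolerance = 1e-10)
  ## invariant to flipping the sign convention of any single IV
  gf <- g; Gf <- 0.7 * g + 0.03
  gf[4] <- -gf[4]; Gf[4] <- -Gf[4]
  e3 <- mrEgger(makeH(gf, Gf, seO = 0.05))
  expect_equal(e3@beta, e2@beta)
  expect_equal(e3@extra$intercept, e2@extra$intercept)
  expect_error(mrEgger(makeH(c(1, 2), c(1, 2))), ">= 3")
})

test_that("weighted median interpolates correctly and resists 40% invalid IVs", {
  ## equal weights, ratios 1,2,3 -> 2
  h <- makeH(rep(1, 3), c(1, 2, 3), seO = 0.1)
  expect_equal(weightedMedian(h, nBoot = 50, seed = 1)@beta, 2)
  ## near-total dominance: estimate approaches the dominant ratio
  hd <- makeH(c(10, 0.1, 0.1), c(10 * 1.5, 0.3, 0.4), seO = 0.1)
  expect_equal(weightedMedian(hd, nBoot = 50, seed = 1)@beta, 1.5,
               tolerance = 0.01)
  ## breakdown property: 40% grossly pleiotropic IVs (direct effects ten
  ## times the causal signal, balanced so InSIDE holds) where IVW fails
  sim <- simulateIvData(mrSimConfig(nIV = 20, propInvalid = 0.4,
                                    pleiotropyMode = "balanced",
                                    pleiotropySd = 0.3, seed = 31))
  h40 <- harmonizePair(sim$exposure, sim$outcome)
  wm <- weightedMedian(h40, nBoot = 200, seed = 1)
  ivw <- mrIvw(h40, "fixed")
  expect_lt(abs(wm@beta - (-0.6)), 2 * wm@se)
  expect_gt(abs(ivw@beta - (-0.6)), 3 * ivw@se)
})

test_that("weighted mode finds the plurality cluster and ignores IV order", {
  ## all ratios equal: return that ratio
  hc <- makeH(rep(1, 4), rep(0.8, 4), seO = 0.1)
  expect_equal(weightedMode(hc, nBoot = 20, seed = 1)@beta, 0.8)
  ## 7 valid IVs near 0.5 + 3 outliers near 5
  set.seed(3)
  ratios <- c(0.5 + rnorm(7, 0, 0.02), 5 + rnorm(3, 0, 0.02))
  hm <- makeH(rep(1, 10), ratios, seO = 0.1)
  est <- weightedMode(hm, nBoot = 50, seed = 1)
  expect_lt(abs(est@beta - 0.5), 0.1)
  ## grid-argmax oracle at full resolution
  wr <- waldRatios(hm)
  oracleGrid <- seq(min(wr$ratio) - 1, max(wr$ratio) + 1, length.out = 20000)
  w <- wr$weight / sum(wr$weight)
  bw <- 0.9 * min(sd(wr$ratio), IQR(wr$ratio) / 1.34) * 10^(-1 / 5)
  dens <- vapply(oracleGrid, function(x)
    sum(w * dnorm((x - wr$ratio) / bw)), numeric(1))
  ## equal weights here, so weighted and unweighted spread coincide
  expect_lt(abs(est@beta - oracleGrid[which.max(dens)]), 0.05)
  ## order invariance
  perm <- sample(10)
  est2 <- weightedMode(makeH(rep(1, 10)[perm], ratios[perm], seO = 0.1),
                       nBoot = 50, seed = 1)
  expect_equal(est2@beta, est@beta)
})

test_that("RAPS collapses to IVW without pleiotropy and detects overdispersion", {
  h <- simStudy(41)$h
  raps <- mrRaps(h)
  ivw <- mrIvw(h, "fixed")
  expect_lt(abs(raps@beta - ivw@beta), 0.5 * ivw@se)
  ## overdispersed data: tau2 > 0 and wider CI than fixed IVW
  simO <- simulateIvData(mrSimConfig(nIV = 30, hetSd = 0.005, seed = 42))
  hO <- harmonizePair(simO$exposure, simO$outcome)
  rapsO <- mrRaps(hO)
  expect_gt(rapsO@extra$tau2, 0)
  expect_gt(rapsO@se, mrIvw(hO, "fixed")@se)
  ## profile grid oracle: the optimizer's argmax matches a grid search
  grid <- seq(rapsO@beta - 0.2, rapsO@beta + 0.2, length.out = 401)
  g <- exposureBeta(hO)[, 1]; seG <- exposureSE(hO)[, 1]
  G <- outcomeBeta(hO); seO <- outcomeSE(hO)
  tau2 <- rapsO@extra$tau2
  prof <- vapply(grid, function(b) {
    v <- seO^2 + b^2 * seG^2 + tau2
    -0.5 * sum((G - b * g)^2 / v) - 0.5 * sum(log(v))
  }, numeric(1))
  expect_lt(abs(grid[which.max(prof)] - rapsO@beta), diff(grid[1:2]) * 2)
  ## huber loss accepted
  expect_s4_class(mrRaps(h, loss = "huber"), "MREstimate")
})

test_that("every estimator is sign-equivariant in the exposure", {
  s <- simStudy(8)
  h <- s$h
  hNeg <- harmonizedSet(-exposureBeta(h)[, 1], exposureSE(h)[, 1],
                        outcomeBeta(h), outcomeSE(h))
  fits <- list(
    c(mrIvw(h, "fixed")@beta, mrIvw(hNeg, "fixed")@beta),
    c(mrEgger(h)@beta, mrEgger(hNeg)@beta),
    c(weightedMedian(h, nBoot = 50, seed = 1)@beta,
      weightedMedian(hNeg, nBoot = 50, seed = 1)@beta),
    c(weightedMode(h, nBoot = 50, seed = 1)@beta,
      weightedMode(hNeg, nBoot = 50, seed = 1)@beta),
    c(mrRaps(h)@beta, mrRaps(hNeg)@beta))
  for (f in fits) expect_equal(f[1], -f[2], tolerance = 1e-6)
})
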