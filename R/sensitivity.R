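#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` over the Wald ratios, with
#' df = n_iv - 1 and an upper-tail chi-square p-value. By default
#' `beta` is the fixed-effect IVW estimate, making Q exactly the weighted
#' residual sum of squares of the IVW fit.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 2 instruments
#'   (a single instrument returns Q = 0 with df = 0 and p = NA).
#' @param beta optional reference estimate; default fixed-effect IVW.
#' @return list `Q, df, p`.
#' @export
cochranQ <- function(h, beta = NULL) {
  wr <- waldRatios(h)
  if (is.null(beta)) beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  Q <- sum(wr$weight * (wr$ratio - beta)^2)
  df <- nrow(wr) - 1L
  p <- if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  list(Q = Q, df = df, p = p)
}

## Leave-one-out fixed-effect IVW slopes on the outcome scale
## (weighted-through-origin regression of G on g, weights 1/seO^2),
## vectorized via totals.
looSlopes <- function(g, G, seO) {
  wnum <- g * G / seO^2
  wden <- g^2 / seO^2
  (sum(wnum) - wnum) / (sum(wden) - wden)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed weighted residual sum of squares
#' `RSS = sum_j w_j (Gammahat_j - beta_{-j} gammahat_j)^2` (leave-one-out
#' IVW slopes beta_{-j}, weights 1/se_Gamma^2) is compared with its
#' distribution over `nSim` parametric simulations of the summary
#' statistics under the no-pleiotropy model. Per-SNP outlier p-values are
#' the analogous tail fractions of each SNP's residual contribution;
#' instruments with p below `outlierP` are removed and the filtered set is
#' returned for re-estimation. Empirical p-values use add-one smoothing, so
#' the global p lies in [1/(nSim+1), 1].
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 4 instruments.
#' @param nSim number of simulated distributions, default 1000.
#' @param outlierP per-SNP removal threshold, default 0.05.
#' @param seed RNG seed.
#' @return list `globalP`, `outliers` (data.frame `snp, p`), `filtered`
#'   (the input minus flagged SNPs, order preserved) and `perSnpP`.
#' @export
mrPresso <- function(h, nSim = 1000, outlierP = 0.05, seed = 1) {
  assertUnivariable(h)
  n <- nIV(h)
  if (n < 4) stop("MR-PRESSO needs >= 4 instruments")
  set.seed(seed)
  g0 <- h@betaExposure[, 1]; seG <- h@seExposure[, 1]
  G0 <- h@betaOutcome; seO <- h@seOutcome
  w <- 1 / seO^2

  bLoo <- looSlopes(g0, G0, seO)
  resObs <- w * (G0 - bLoo * g0)^2
  rssObs <- sum(resObs)

  exceedGlobal <- 0L
  exceedSnp <- integer(n)
  mu <- bLoo * g0  # expected outcome effects under the fitted model
  for (s in seq_len(nSim)) {
    gs <- stats::rnorm(n, g0, seG)
    Gs <- stats::rnorm(n, mu, seO)
    bs <- looSlopes(gs, Gs, seO)
    rs <- w * (Gs - bs * gs)^2
    exceedGlobal <- exceedGlobal + (sum(rs) >= rssObs)
    exceedSnp <- exceedSnp + (rs >= resObs)
  }
  globalP <- (1 + exceedGlobal) / (nSim + 1)
  perSnpP <- (1 + exceedSnp) / (nSim + 1)
  flagged <- perSnpP < outlierP
  outliers <- data.frame(snp = h@snps$snp[flagged], p = perSnpP[flagged],
                         stringsAsFactors = FALSE)
  list(globalP = globalP, outliers = outliers,
       filtered = if (any(flagged)) h[!flagged] else h,
       perSnpP = perSnpP)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the outcome: `r2 = sum_j t_j^2/(t_j^2 + n - 2)` per trait. The causal
#' direction exposure -> outcome is supported when the exposure r2 exceeds
#' the outcome r2; the p-value compares the Fisher-transformed sqrt(r2)
#' correlations with a two-independent-samples z-test at the two GWAS
#' sample sizes. For binary traits r2 is computed on the observed log-odds
#' scale.
#'
#' @param h a single-exposure [HarmonizedSet-class].
#' @param nExposure,nOutcome GWAS sample sizes; default from the set.
#' @return list `r2Exposure, r2Outcome, directionOk, p`.
#' @export
steigerTest <- function(h, nExposure = NULL, nOutcome = NULL) {
  assertUnivariable(h)
  n1 <- nExposure %||% h@nExposure[1]
  n2 <- nOutcome %||% h@nOutcome
  if (!is.finite(n1) || !is.finite(n2)) stop("GWAS sample sizes missing")
  r2e <- sum(snpR2(h@betaExposure[, 1], h@seExposure[, 1], n1))
  r2o <- sum(snpR2(h@betaOutcome, h@seOutcome, n2))
  z <- (atanh(sqrt(min(r2e, 1 - 1e-12))) -
        atanh(sqrt(min(r2o, 1 - 1e-12)))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r2Exposure = r2e, r2Outcome = r2o, directionOk = r2e > r2o,
       p = twoSidedNormalP(z))
}

#' Leave-one-out IVW series
#'
#' One IVW estimate per omitted instrument, plus a `robust` attribute that
#' is TRUE when every reduced-set CI agrees with the full estimate on
#' whether zero is excluded.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @param model IVW model passed to [mrIvw()].
#' @return data.frame `snp_removed, beta, se, ci_low, ci_high, pvalue` with
#'   attributes `full` (the all-IV estimate) and `robust`.
#' @export
leaveOneOut <- function(h, model = "fixed") {
  n <- nIV(h)
  if (n < 3) stop("leave-one-out needs >= 3 instruments")
  full <- mrIvw(h, model)
  rows <- lapply(seq_len(n), function(j) {
    e <- mrIvw(h[-j], model)
    data.frame(snp_removed = h@snps$snp[j], beta = e@beta, se = e@se,
               ci_low = e@ciLow, ci_high = e@ciHigh, pvalue = e@pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fullExcludes <- full@ciLow > 0 || full@ciHigh < 0
  looExcludes <- out$ci_low > 0 | out$ci_high < 0
  attr(out, "full") <- full
  attr(out, "robust") <- all(looExcludes == fullExcludes)
  out
}

#' Egger intercept pleiotropy test
#'
#' The intercept of the MR-Egger regression with its SE and t-test p-value
#' (df = n_iv - 2); an intercept compatible with zero (p > 0.05) indicates
#' no directional pleiotropy.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @return list `intercept, se, p`.
#' @export
eggerInterceptTest <- function(h) {
  e <- mrEgger(h)
  list(intercept = e@extra$intercept, se = e@extra$interceptSE,
       p = e@extra$interceptP)
}

#' Full sensitivity suite around a univariable MR analysis
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO, the Steiger
#' directionality test and the leave-one-out series into one report.
#'
#' @param h a single-exposure [HarmonizedSet-class].
#' @param pressoNSim MR-PRESSO simulated distributions (0 skips PRESSO,
#'   e.g. when fewer than 4 instruments are available).
#' @param seed RNG seed.
#' @return a [SensitivityReport-class].
#' @export
sensitivitySuite <- function(h, pressoNSim = 1000, seed = 1) {
  q <- cochranQ(h)
  eg <- eggerInterceptTest(h)
  st <- steigerTest(h)
  loo <- leaveOneOut(h)
  if (pressoNSim > 0 && nIV(h) >= 4) {
    pr <- mrPresso(h, nSim = pressoNSim, seed = subSeed(seed, "presso"))
    gp <- pr$globalP; po <- pr$outliers
  } else {
    gp <- NA_real_
    po <- data.frame(snp = character(), p = numeric())
  }
  new("SensitivityReport", Q = q$Q, qDf = as.numeric(q$df), qP = q$p,
      eggerIntercept = eg$intercept, eggerInterceptSE = eg$se,
      eggerInterceptP = eg$p, pressoGlobalP = gp, pressoOutliers = po,
      steiger = st, loo = loo)
}
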