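#' Per-instrument Wald ratios
#'
#' ratio_j = Gammahat_j / gammahat_j with first-order SE
#' se_j = se_Gamma_j / |gammahat_j| and inverse-variance weight
#' w_j = 1/se_j^2 = gammahat_j^2 / se_Gamma_j^2.
#'
#' @param h a single-exposure [HarmonizedSet-class].
#' @return data.frame `snp, ratio, se, weight`.
#' @export
waldRatios <- function(h) {
  assertUnivariable(h)
  g <- h@betaExposure[, 1]
  if (any(g == 0))
    stop("zero exposure effect for SNP(s): ",
         paste(h@snps$snp[g == 0], collapse = ", "))
  data.frame(snp = h@snps$snp,
             ratio = h@betaOutcome / g,
             se = h@seOutcome / abs(g),
             weight = g^2 / h@seOutcome^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Meta-analysis of the Wald ratios: beta = sum(w_j ratio_j)/sum(w_j) with
#' w_j = gammahat_j^2/se_Gamma_j^2 — algebraically identical to weighted
#' least squares of the outcome effects on the exposure effects through the
#' origin with weights 1/se_Gamma^2. The fixed-effect SE is
#' (sum w_j)^{-1/2}; the random-effects (multiplicative) SE inflates it by
#' sqrt(max(1, Q/(n-1))).
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 1 instrument
#'   (one instrument degenerates to the Wald ratio).
#' @param model `"fixed"` or `"random"`.
#' @return an [MREstimate-class]; `extra$Q` holds the Cochran statistic.
#' @export
mrIvw <- function(h, model = c("fixed", "random")) {
  model <- match.arg(model)
  wr <- waldRatios(h)
  W <- sum(wr$weight)
  if (W <= 0) stop("zero total weight")
  beta <- sum(wr$weight * wr$ratio) / W
  se <- sqrt(1 / W)
  Q <- sum(wr$weight * (wr$ratio - beta)^2)
  n <- nrow(wr)
  if (model == "random" && n > 1) se <- se * sqrt(max(1, Q / (n - 1)))
  newMREstimate(paste0("ivw_", model), n, beta, se,
                extra = list(Q = Q))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, after orienting every instrument so its
#' exposure effect is positive (both betas negated where needed). The slope
#' is the causal estimate; a non-zero intercept signals directional
#' pleiotropy. Weights are 1/se_Gamma^2; SEs are scaled by
#' sqrt(max(1, RSS_w/(n-2))) and p-values use the t distribution on n-2 df.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @return an [MREstimate-class] with `extra$intercept`,
#'   `extra$interceptSE`, `extra$interceptP`.
#' @export
mrEgger <- function(h) {
  assertUnivariable(h)
  n <- nIV(h)
  if (n < 3) stop("MR-Egger needs >= 3 instruments")
  g <- h@betaExposure[, 1]
  G <- h@betaOutcome
  flip <- g < 0
  g[flip] <- -g[flip]; G[flip] <- -G[flip]
  w <- 1 / h@seOutcome^2
  fit <- wlsFit(cbind(intercept = 1, slope = g), G, w)
  scale <- sqrt(max(1, fit$rss / (n - 2)))
  se <- fit$se * scale
  tstat <- fit$coef / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- stats::qt(0.975, df = n - 2)
  newMREstimate("mr_egger", n, beta = fit$coef[["slope"]],
                se = se[["slope"]], pvalue = p[["slope"]],
                ci = fit$coef[["slope"]] + c(-1, 1) * q * se[["slope"]],
                extra = list(intercept = fit$coef[["intercept"]],
                             interceptSE = se[["intercept"]],
                             interceptP = p[["intercept"]]))
}

## Point estimate of the weighted median given ratios and weights:
## linear interpolation of the sorted ratios at standardized cumulative
## weight 1/2.
weightedMedianPoint <- function(ratio, w) weightedQuantile(ratio, w, 0.5)

## Parametric bootstrap over the summary statistics; returns the SD of the
## replicated point estimates. `pointFun(g, G, seG, seO)` -> scalar.
parametricBootstrapSE <- function(h, pointFun, nBoot, seed) {
  set.seed(seed)
  g0 <- h@betaExposure[, 1]; seG <- h@seExposure[, 1]
  G0 <- h@betaOutcome; seO <- h@seOutcome
  n <- length(g0)
  est <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    g <- stats::rnorm(n, g0, seG)
    G <- stats::rnorm(n, G0, seO)
    est[b] <- pointFun(g, G, seG, seO)
  }
  stats::sd(est)
}

#' Weighted-median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Ratios are sorted; the estimate interpolates the ratio at standardized
#' cumulative weight 1/2 (s_j = (cumsum(w) - w_j/2)/sum(w)). The SE is the
#' SD of the estimate over `nBoot` parametric-bootstrap resamples of the
#' summary statistics.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @param nBoot bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an [MREstimate-class].
#' @export
weightedMedian <- function(h, nBoot = 1000, seed = 1) {
  assertUnivariable(h)
  n <- nIV(h)
  if (n < 3) stop("weighted median needs >= 3 instruments")
  wr <- waldRatios(h)
  if (all(wr$weight == 0)) stop("degenerate weights")
  beta <- weightedMedianPoint(wr$ratio, wr$weight)
  se <- parametricBootstrapSE(h, function(g, G, seG, seO) {
    weightedMedianPoint(G / g, g^2 / seO^2)
  }, nBoot, seed)
  newMREstimate("weighted_median", n, beta, se)
}

## Mode point estimate: argmax over a fine grid of the weighted normal
## kernel density of the ratios; bandwidth by the modified Silverman rule
## on the weighted spread, scaled by phi.
weightedModePoint <- function(ratio, w, phi = 1, gridN = 512) {
  w <- w / sum(w)
  mu <- sum(w * ratio)
  wsd <- sqrt(sum(w * (ratio - mu)^2))
  wiqr <- diff(weightedQuantile(ratio, w, c(0.25, 0.75)))
  spread <- min(wsd, wiqr / 1.34)
  bw <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])  # all ratios identical
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = gridN)
  dens <- colSums(w * exp(-0.5 * ((outer(ratio, grid, "-")) / bw)^2))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Clusters instruments by the similarity of their ratio estimates via a
#' weighted kernel density and takes the density argmax — consistent when
#' the largest cluster consists of valid instruments even if most are
#' invalid. Bandwidth is `phi * 0.9 * min(SD, IQR/1.34) * n^{-1/5}` on the
#' inverse-variance-weighted spread of the ratios. SE by parametric
#' bootstrap.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @param phi bandwidth multiplier, default 1.
#' @param nBoot,seed bootstrap control, as in [weightedMedian()].
#' @return an [MREstimate-class].
#' @export
weightedMode <- function(h, phi = 1, nBoot = 1000, seed = 1) {
  assertUnivariable(h)
  n <- nIV(h)
  if (n < 3) stop("weighted mode needs >= 3 instruments")
  wr <- waldRatios(h)
  beta <- weightedModePoint(wr$ratio, wr$weight, phi = phi)
  se <- parametricBootstrapSE(h, function(g, G, seG, seO) {
    weightedModePoint(G / g, g^2 / seO^2, phi = phi, gridN = 256)
  }, nBoot, seed)
  newMREstimate("weighted_mode", n, beta, se)
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Maximizes the adjusted profile log-likelihood
#' `sum_j [-rho(t_j)/2 - log(v_j)/2]` with
#' `t_j = (Gammahat_j - beta*gammahat_j)/sqrt(v_j)` and
#' `v_j = se_Gamma_j^2 + beta^2 se_gamma_j^2 + tau^2`, jointly over the
#' causal effect beta and the overdispersion tau^2 >= 0. `rho` is the
#' squared loss by default or the Huber loss (k = 1.345). The SE comes from
#' the observed information of the profile in beta.
#'
#' @param h a single-exposure [HarmonizedSet-class] with >= 3 instruments.
#' @param overdispersion estimate tau^2 (default TRUE); when FALSE tau^2
#'   is fixed at zero.
#' @param loss `"l2"` or `"huber"`.
#' @return an [MREstimate-class] with `extra$tau2`.
#' @export
mrRaps <- function(h, overdispersion = TRUE, loss = c("l2", "huber")) {
  assertUnivariable(h)
  loss <- match.arg(loss)
  n <- nIV(h)
  if (n < 3) stop("RAPS needs >= 3 instruments")
  g <- h@betaExposure[, 1]; seG <- h@seExposure[, 1]
  G <- h@betaOutcome; seO <- h@seOutcome
  k <- 1.345
  rho <- if (loss == "l2") function(t) t^2 else
    function(t) ifelse(abs(t) <= k, t^2, 2 * k * abs(t) - k^2)

  negll <- function(beta, tau2) {
    v <- seO^2 + beta^2 * seG^2 + tau2
    t <- (G - beta * g) / sqrt(v)
    0.5 * sum(rho(t)) + 0.5 * sum(log(v))
  }
  start <- mrIvw(h, "fixed")@beta
  if (overdispersion) {
    obj <- function(par) negll(par[1], exp(par[2]))
    ## log-parameterize tau2; start near zero overdispersion
    fit <- stats::optim(c(start, log(stats::var(G - start * g) / 4 + 1e-12)),
                        obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$convergence != 0)
      stop("RAPS optimizer failed to converge (code ", fit$convergence,
           "): ", fit$message %||% "")
    beta <- fit$par[1]
    tau2 <- exp(fit$par[2])
    if (tau2 < 1e-10) tau2 <- 0
  } else {
    fit <- stats::optimize(function(b) negll(b, 0),
                           interval = start + c(-1, 1) *
                             max(1, 10 * abs(start)))
    beta <- fit$minimum
    tau2 <- 0
  }
  ## observed information of the profile in beta: numeric second
  ## derivative with tau^2 re-profiled at each evaluation
  profile <- function(b) {
    if (!overdispersion || tau2 == 0) return(negll(b, tau2))
    stats::optimize(function(lt) negll(b, exp(lt)),
                    interval = log(tau2) + c(-8, 8))$objective
  }
  eps <- max(1e-5, 1e-4 * abs(beta))
  d2 <- (profile(beta + eps) - 2 * profile(beta) + profile(beta - eps)) /
    eps^2
  if (!is.finite(d2) || d2 <= 0)
    stop("RAPS information matrix not positive at the optimum")
  se <- sqrt(1 / d2)
  newMREstimate("raps", n, beta, se, extra = list(tau2 = tau2))
}

#' Run all five univariable estimators
#'
#' Convenience wrapper returning the standard results table (one row per
#' method). IVW uses the random-effects (multiplicative) model when the
#' Cochran Q p-value falls below `hetP`, the fixed-effect model otherwise.
#'
#' @param h a single-exposure [HarmonizedSet-class].
#' @param seed seed for the bootstrap-based methods.
#' @param nBoot bootstrap replicates for median and mode.
#' @param hetP heterogeneity p-value below which IVW switches to the
#'   random-effects model, default 0.05.
#' @return data.frame `method, n_iv, beta, se, ci_low, ci_high, pvalue`.
#' @export
mrAllMethods <- function(h, seed = 1, nBoot = 1000, hetP = 0.05) {
  q <- cochranQ(h)
  ivwModel <- if (is.finite(q$p) && q$p < hetP) "random" else "fixed"
  ests <- list(
    mrIvw(h, ivwModel),
    weightedMedian(h, nBoot = nBoot, seed = subSeed(seed, "wmedian")),
    mrEgger(h),
    weightedMode(h, nBoot = nBoot, seed = subSeed(seed, "wmode")),
    mrRaps(h))
  do.call(rbind, lapply(ests, function(e)
    data.frame(method = e@method, n_iv = e@nIV, beta = e@beta, se = e@se,
               ci_low = e@ciLow, ci_high = e@ciHigh, pvalue = e@pvalue,
               stringsAsFactors = FALSE)))
}
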