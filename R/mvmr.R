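#' Multivariable MR fit
#'
#' Weighted least squares of the outcome effects on the matrix of exposure
#' effects (weights 1/se_Gamma^2), estimating each exposure's direct effect
#' conditional on the others. The IVW variant has no intercept; the Egger
#' variant adds one after orienting every instrument so the reference
#' exposure's effect is positive (the whole row, outcome included, is
#' negated). The adjusted Cochran Q is the weighted residual sum of squares
#' with df = n_iv - K (IVW) or n_iv - K - 1 (Egger); per-exposure SEs are
#' inflated by sqrt(max(1, Q/df)).
#'
#' @param mh a multi-exposure [HarmonizedSet-class] from
#'   [harmonizeMulti()] (a single-exposure set reduces exactly to
#'   univariable IVW).
#' @param method `"ivw"` (primary) or `"egger"` (use when the MVMR-Egger
#'   intercept test signals directional pleiotropy).
#' @param orientOn index or name of the exposure used to orient rows for
#'   the Egger variant, default the first.
#' @return an [MVMRResult-class].
#' @export
mvmrFit <- function(mh, method = c("ivw", "egger"), orientOn = 1L) {
  method <- match.arg(method)
  X <- mh@betaExposure
  y <- mh@betaOutcome
  w <- 1 / mh@seOutcome^2
  n <- nrow(X); K <- ncol(X)
  if (is.character(orientOn)) orientOn <- match(orientOn, colnames(X))
  minIV <- K + 1 + (method == "egger")
  if (n < minIV) stop("need n_iv > n_exposures",
                      if (method == "egger") " + 1")

  if (method == "egger") {
    flip <- X[, orientOn] < 0
    X[flip, ] <- -X[flip, , drop = FALSE]
    y[flip] <- -y[flip]
    design <- cbind(`(intercept)` = 1, X)
  } else design <- X

  qrX <- qr(design * sqrt(w))
  if (qrX$rank < ncol(design)) {
    cc <- stats::cor(X)
    diag(cc) <- 0
    pair <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("rank-deficient exposure matrix; collinear exposures: ",
         paste(colnames(X)[pair], collapse = " and "))
  }
  fit <- wlsFit(design, y, w)
  df <- n - ncol(design)
  Q <- fit$rss
  qP <- stats::pchisq(Q, df, lower.tail = FALSE)
  scale <- sqrt(max(1, Q / df))
  se <- fit$se * scale

  coefIdx <- if (method == "egger") seq_len(K) + 1L else seq_len(K)
  beta <- fit$coef[coefIdx]; betaSE <- se[coefIdx]
  zq <- stats::qnorm(0.975)
  est <- data.frame(exposure = colnames(X), beta = unname(beta),
                    se = unname(betaSE),
                    ci_low = unname(beta - zq * betaSE),
                    ci_high = unname(beta + zq * betaSE),
                    pvalue = twoSidedNormalP(unname(beta / betaSE)),
                    stringsAsFactors = FALSE)
  if (method == "egger") {
    i0 <- fit$coef[1]; i0se <- se[1]
    iP <- 2 * stats::pt(-abs(i0 / i0se), df = df)
  } else {
    i0 <- NA_real_; i0se <- NA_real_; iP <- NA_real_
  }
  new("MVMRResult", estimates = est, method = method, nIV = as.integer(n),
      Q = Q, qDf = as.numeric(df), qP = qP, intercept = unname(i0),
      interceptSE = unname(i0se), interceptP = unname(iP))
}
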