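## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sub-seed derivation: one user seed fans out to per-stage
## seeds without correlated streams. Kept below 2^31 - 1.
subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483587) + 1L
}

## Weighted quantile by linear interpolation of the standardized cumulative
## weight (S_j = (cumsum(w) - w/2) / sum(w)), the same rule the weighted
## median estimator uses.
weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, x, xout = probs, rule = 2, ties = "ordered")$y
}

## Weighted least squares via the QR of the scaled design; returns
## coefficients, their model-based SEs (unit dispersion), weighted RSS and
## residual df. `x` is the design matrix (include the intercept column
## yourself if wanted).
wlsFit <- function(x, y, w) {
  sw <- sqrt(w)
  xs <- x * sw
  qrx <- qr(xs)
  if (qrx$rank < ncol(x))
    stop("rank-deficient design in weighted regression")
  coef <- qr.coef(qrx, y * sw)
  res <- y - drop(x %*% coef)
  rss <- sum(w * res^2)
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(xtxinv))
  names(se) <- names(coef)
  list(coef = coef, se = se, rss = rss,
       df = length(y) - ncol(x), residuals = res, xtxinv = xtxinv)
}

twoSidedNormalP <- function(z) 2 * stats::pnorm(-abs(z))

ciNormal <- function(beta, se, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(beta - q * se, beta + q * se)
}

newMREstimate <- function(method, n, beta, se, pvalue = NULL, extra = list(),
                          ci = NULL) {
  if (is.null(ci)) ci <- ciNormal(beta, se)
  if (is.null(pvalue)) pvalue <- twoSidedNormalP(beta / se)
  new("MREstimate", method = method, nIV = as.integer(n), beta = beta,
      se = se, ciLow = ci[1], ciHigh = ci[2], pvalue = pvalue, extra = extra)
}

## Single-exposure guard used by the univariable estimators.
assertUnivariable <- function(h) {
  if (ncol(h@betaExposure) != 1L)
    stop("this estimator requires a single-exposure HarmonizedSet; ",
         "use mvmrFit() for multiple exposures")
  invisible(h)
}

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complementAllele <- function(a) unname(.DNA_COMPLEMENT[a])
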