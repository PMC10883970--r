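#' @import methods
NULL

## Canonical per-SNP summary-statistic columns shared by readers, simulators
## and the harmonizer. `eaf` may be NA; everything else is required.
.SUMSTAT_COLS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

.DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' SummaryDataset: one trait's GWAS summary statistics
#'
#' Container for per-variant association statistics of a single GWAS
#' (one row per SNP: alleles, effect-allele frequency, effect estimate with
#' standard error, p-value and sample size) together with trait metadata.
#' For binary traits the `beta` column holds log odds ratios.
#'
#' @slot stats data.frame with columns `snp, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n`; `snp` unique.
#' @slot traitName character scalar.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot nTotal total GWAS sample size (may differ from per-SNP `n`).
#' @slot ancestry free-text ancestry label.
#' @export
setClass("SummaryDataset",
  representation(stats = "data.frame", traitName = "character",
                 traitType = "character", nTotal = "numeric",
                 ancestry = "character"),
  prototype(traitType = "quantitative", nTotal = NA_real_,
            ancestry = "European"))

setValidity("SummaryDataset", function(object) {
  st <- object@stats
  msg <- character()
  miss <- setdiff(.SUMSTAT_COLS, names(st))
  if (length(miss))
    msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(st$snp)) msg <- c(msg, "snp ids must be unique")
    if (any(st$se <= 0, na.rm = TRUE)) msg <- c(msg, "all se must be > 0")
    if (any(st$effect_allele == st$other_allele))
      msg <- c(msg, "effect and other allele must differ")
    bad.eaf <- !is.na(st$eaf) & (st$eaf < 0 | st$eaf > 1)
    if (any(bad.eaf)) msg <- c(msg, "eaf must be in [0,1] or NA")
  }
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure and outcome effects on a common effect allele
#'
#' The unit all MR estimators consume. Each row is one instrument whose
#' exposure effect(s) and outcome effect are expressed relative to the same
#' effect allele. Supports K >= 1 exposures; univariable estimators require
#' K = 1, [mvmrFit()] requires K >= 2.
#'
#' @slot snps data.frame: `snp, chrom, pos, effect_allele, other_allele, eaf,
#'   provenance` where provenance is one of `unchanged, flipped,
#'   strand_corrected, proxied`.
#' @slot betaExposure,seExposure n x K matrices of exposure effects / SEs.
#' @slot betaOutcome,seOutcome numeric vectors, length n.
#' @slot nExposure numeric, length K: exposure GWAS sample sizes.
#' @slot nOutcome numeric scalar: outcome GWAS sample size.
#' @slot exposures,outcome trait names.
#' @export
setClass("HarmonizedSet",
  representation(snps = "data.frame",
                 betaExposure = "matrix", seExposure = "matrix",
                 betaOutcome = "numeric", seOutcome = "numeric",
                 nExposure = "numeric", nOutcome = "numeric",
                 exposures = "character", outcome = "character"))

setValidity("HarmonizedSet", function(object) {
  n <- nrow(object@snps)
  msg <- character()
  if (nrow(object@betaExposure) != n || nrow(object@seExposure) != n ||
      length(object@betaOutcome) != n || length(object@seOutcome) != n)
    msg <- c(msg, "row counts of snps/betas/ses disagree")
  if (ncol(object@betaExposure) != ncol(object@seExposure))
    msg <- c(msg, "betaExposure and seExposure must have equal columns")
  if (any(object@seExposure <= 0) || any(object@seOutcome <= 0))
    msg <- c(msg, "all standard errors must be positive")
  if (anyDuplicated(object@snps$snp)) msg <- c(msg, "duplicate snp ids")
  if (length(msg)) msg else TRUE
})

#' MREstimate: one causal-effect estimate
#'
#' Row type of the univariable MR results table: method label, number of
#' instruments, point estimate with normal-theory 95% CI and two-sided
#' p-value, plus method-specific extras (Egger intercept, RAPS tau^2).
#'
#' @slot method character, e.g. `"ivw"`.
#' @slot nIV integer instrument count.
#' @slot beta,se,ciLow,ciHigh,pvalue numeric scalars.
#' @slot extra named list of auxiliary quantities.
#' @export
setClass("MREstimate",
  representation(method = "character", nIV = "integer", beta = "numeric",
                 se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pvalue = "numeric", extra = "list"),
  prototype(extra = list()))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (length(object@se) && is.finite(object@se) && object@se < 0)
    msg <- c(msg, "se must be non-negative")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msg <- c(msg, "CI must bracket beta")
  if (length(msg)) msg else TRUE
})

#' LDReference: pairwise r-squared lookup
#'
#' Virtual base class for LD references. Concrete classes answer
#' [ldR2()] queries (symmetric, r2(a,a) = 1) and expose per-SNP
#' chromosome/position via [ldSnpInfo()] for windowed clumping.
#'
#' @export
setClass("LDReference", representation("VIRTUAL"))

#' @describeIn LDReference-class block-diagonal reference: a constant
#'   pairwise correlation within each block, zero across blocks.
#' @slot snps data.frame `snp, chrom, pos, block`.
#' @slot blockR numeric per-block pairwise correlation r (not r^2).
#' @export
setClass("BlockLDReference", contains = "LDReference",
  representation(snps = "data.frame", blockR = "numeric"))

#' @describeIn LDReference-class explicit sparse pair list, e.g. read from a
#'   3-column TSV; absent pairs score r^2 = 0.
#' @slot snps data.frame `snp, chrom, pos`.
#' @slot pairs environment keyed `"a|b"` (a < b) holding r^2 values.
#' @export
setClass("PairLDReference", contains = "LDReference",
  representation(snps = "data.frame", pairs = "environment"))

#' InstrumentSet: clumped genome-wide-significant instruments
#'
#' Output of [clump()]: the retained index SNPs with their exposure
#' statistics, the selection thresholds actually applied, per-SNP variance
#' explained and the instrument-strength F statistic.
#'
#' @slot snps data.frame of retained rows (canonical sumstat columns).
#' @slot pThreshold,r2Threshold,windowKb selection parameters.
#' @slot r2PerSnp per-instrument variance explained (NA when n missing).
#' @slot fStat F statistic over the summed R^2 (NA when unavailable).
#' @export
setClass("InstrumentSet",
  representation(snps = "data.frame", pThreshold = "numeric",
                 r2Threshold = "numeric", windowKb = "numeric",
                 r2PerSnp = "numeric", fStat = "numeric"))

#' SensitivityReport: diagnostics around a univariable MR fit
#'
#' @slot Q,qDf,qP Cochran heterogeneity statistic, df = n_iv - 1, p.
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptP Egger intercept test.
#' @slot pressoGlobalP MR-PRESSO global test p (NA when not run).
#' @slot pressoOutliers data.frame `snp, p` of flagged instruments.
#' @slot steiger list `r2Exposure, r2Outcome, directionOk, p`.
#' @slot loo data.frame of leave-one-out IVW estimates.
#' @export
setClass("SensitivityReport",
  representation(Q = "numeric", qDf = "numeric", qP = "numeric",
                 eggerIntercept = "numeric", eggerInterceptSE = "numeric",
                 eggerInterceptP = "numeric",
                 pressoGlobalP = "numeric", pressoOutliers = "data.frame",
                 steiger = "list", loo = "data.frame"))

#' MVMRResult: multivariable MR fit
#'
#' @slot estimates data.frame `exposure, beta, se, ciLow, ciHigh, pvalue`.
#' @slot method `"ivw"` or `"egger"`.
#' @slot nIV instrument count.
#' @slot Q,qDf,qP adjusted Cochran heterogeneity (df = n_iv - K for IVW,
#'   n_iv - K - 1 for Egger).
#' @slot intercept,interceptSE,interceptP MVMR-Egger intercept (NA for IVW).
#' @export
setClass("MVMRResult",
  representation(estimates = "data.frame", method = "character",
                 nIV = "integer", Q = "numeric", qDf = "numeric",
                 qP = "numeric", intercept = "numeric",
                 interceptSE = "numeric", interceptP = "numeric"))

setValidity("MVMRResult", function(object) {
  k <- nrow(object@estimates)
  want <- object@nIV - k - (object@method == "egger")
  if (length(object@qDf) && is.finite(object@qDf) && object@qDf != want)
    return(sprintf("qDf must be %d (n_iv - K%s)", want,
                   if (object@method == "egger") " - 1" else ""))
  TRUE
})

#' MediationResult: two-step MR mediation by product of coefficients
#'
#' @slot betaTotal exposure -> outcome total effect.
#' @slot betaXM exposure -> mediator effect (log-odds scale when the
#'   mediator is binary).
#' @slot betaMY mediator -> outcome effect.
#' @slot indirect product betaXM * betaMY.
#' @slot seIndirect delta-method SE (an extension: the source quantities
#'   carry no published SE for the product).
#' @slot proportion percent of the total effect mediated, 100*indirect/total.
#' @slot mediatorBinary logical flag recording the betaXM scale.
#' @slot steps list of the three MREstimate objects, for provenance.
#' @export
setClass("MediationResult",
  representation(betaTotal = "numeric", betaXM = "numeric",
                 betaMY = "numeric", indirect = "numeric",
                 seIndirect = "numeric", proportion = "numeric",
                 mediatorBinary = "logical", steps = "list"))

#' LdscResult: bivariate LD score regression estimates
#'
#' @slot h2 numeric length-2: SNP heritabilities of the two traits.
#' @slot h2SE block-jackknife SEs of the heritabilities.
#' @slot gencov genetic covariance.
#' @slot rg genetic correlation gencov / sqrt(h2_1 * h2_2).
#' @slot rgSE block-jackknife SE of rg.
#' @slot rgP two-sided normal p for rg = 0.
#' @slot intercepts numeric length-3: univariate intercepts and the
#'   bivariate (cross-trait) intercept.
#' @slot nBlocks jackknife block count; nSnps SNPs used after filtering.
#' @export
setClass("LdscResult",
  representation(h2 = "numeric", h2SE = "numeric", gencov = "numeric",
                 rg = "numeric", rgSE = "numeric", rgP = "numeric",
                 intercepts = "numeric", nBlocks = "integer",
                 nSnps = "integer"))

#' ConjFdrResult: conjunctional FDR cross-trait overlap
#'
#' @slot table data.frame per SNP: `snp, chrom, pos, p1, p2, cfdr12
#'   (FDR of trait 1 given trait 2), cfdr21, conjfdr = max of the two`.
#' @slot grid list with the stratified monotone lookup grids
#'   (`p1Breaks, p2Breaks, grid12, grid21`).
#' @slot loci data.frame of clumped lead SNPs at conjfdr < threshold.
#' @slot threshold the locus threshold applied.
#' @export
setClass("ConjFdrResult",
  representation(table = "data.frame", grid = "list", loci = "data.frame",
                 threshold = "numeric"))

#' MRSimConfig: generative model for paired two-sample MR summary statistics
#'
#' Parameters of the instrument-level model: per-IV exposure effects
#' gamma_j ~ N(gammaMean, gammaSd^2), direct (pleiotropic) effects alpha_j
#' on a `propInvalid` fraction of IVs, outcome effects
#' Gamma_j = trueBeta * gamma_j + alpha_j + N(0, hetSd^2), and sampling
#' noise with SEs 1/sqrt(n) per trait.
#'
#' @export
setClass("MRSimConfig",
  representation(nIV = "integer", trueBeta = "numeric",
                 gammaMean = "numeric", gammaSd = "numeric",
                 nExposure = "numeric", nOutcome = "numeric",
                 pleiotropyMode = "character", pleiotropySd = "numeric",
                 pleiotropyMean = "numeric", hetSd = "numeric",
                 propInvalid = "numeric", palindromicFrac = "numeric",
                 binaryOutcome = "logical", seed = "integer"))

setValidity("MRSimConfig", function(object) {
  msg <- character()
  num <- c(object@trueBeta, object@gammaMean, object@gammaSd,
           object@nExposure, object@nOutcome, object@pleiotropySd,
           object@pleiotropyMean, object@hetSd, object@propInvalid,
           object@palindromicFrac)
  if (any(!is.finite(num))) msg <- c(msg, "config values must be finite")
  if (object@nIV < 1L) msg <- c(msg, "nIV must be >= 1")
  if (object@propInvalid < 0 || object@propInvalid > 1)
    msg <- c(msg, "propInvalid must be in [0,1]")
  if (object@gammaSd < 0 || object@pleiotropySd < 0 || object@hetSd < 0)
    msg <- c(msg, "SDs must be >= 0")
  if (object@nExposure < 2 || object@nOutcome < 2)
    msg <- c(msg, "sample sizes must be >= 2")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional",
                                    "correlated"))
    msg <- c(msg, "unknown pleiotropyMode")
  if (object@palindromicFrac < 0 || object@palindromicFrac > 1)
    msg <- c(msg, "palindromicFrac must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' GenomeSimConfig: generative model for genome-wide two-trait z-scores
#'
#' Encodes the LD score regression expectation: per-SNP z-scores for two
#' traits drawn jointly with E[z1^2] = n1*h2_1*l_j/m + 1 and
#' E[z1*z2] = sqrt(n1*n2)*rg*sqrt(h2_1*h2_2)*l_j/m, where l_j is the SNP's
#' LD score from a block LD structure (no sample overlap).
#'
#' @export
setClass("GenomeSimConfig",
  representation(mSnps = "integer", n1 = "numeric", n2 = "numeric",
                 h2_1 = "numeric", h2_2 = "numeric", rg = "numeric",
                 blockSize = "integer", withinBlockR = "numeric",
                 seed = "integer"))

setValidity("GenomeSimConfig", function(object) {
  msg <- character()
  if (object@mSnps < 1L) msg <- c(msg, "mSnps must be >= 1")
  if (object@h2_1 < 0 || object@h2_1 > 1 || object@h2_2 < 0 ||
      object@h2_2 > 1)
    msg <- c(msg, "heritabilities must be in [0,1]")
  if (abs(object@rg) > 1) msg <- c(msg, "rg must be in [-1,1]")
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msg <- c(msg, "withinBlockR must be in [0,1)")
  if (object@blockSize < 1L) msg <- c(msg, "blockSize must be >= 1")
  if (length(msg)) msg else TRUE
})
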