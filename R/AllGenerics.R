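#' Pairwise LD lookup
#'
#' Returns r^2 between `a` and each element of `b` (vectorized over `b`).
#' Symmetric; `ldR2(ld, x, x)` is 1; pairs unknown to the reference are 0.
#'
#' @param ld an [LDReference-class] object.
#' @param a single SNP id.
#' @param b character vector of SNP ids.
#' @return numeric vector of r^2 values, same length as `b`.
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))

#' Per-SNP chromosome/position table of an LD reference
#' @param ld an [LDReference-class] object.
#' @return data.frame with columns `snp, chrom, pos`.
#' @export
setGeneric("ldSnpInfo", function(ld) standardGeneric("ldSnpInfo"))

#' @rdname accessors
#' @export
setGeneric("nIV", function(x) standardGeneric("nIV"))

#' @rdname accessors
#' @export
setGeneric("exposureBeta", function(x) standardGeneric("exposureBeta"))

#' @rdname accessors
#' @export
setGeneric("exposureSE", function(x) standardGeneric("exposureSE"))

#' @rdname accessors
#' @export
setGeneric("outcomeBeta", function(x) standardGeneric("outcomeBeta"))

#' @rdname accessors
#' @export
setGeneric("outcomeSE", function(x) standardGeneric("outcomeSE"))

#' @rdname accessors
#' @export
setGeneric("snpTable", function(x) standardGeneric("snpTable"))

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' Accessors for somnimr data classes
#'
#' `nIV` gives the instrument count, `exposureBeta`/`exposureSE` the
#' exposure effect matrix (n x K), `outcomeBeta`/`outcomeSE` the outcome
#' effects, `snpTable` the per-SNP annotation table and `traitName` the
#' trait label of a [SummaryDataset-class].
#'
#' @param x a somnimr object.
#' @name accessors
NULL

setMethod("nIV", "HarmonizedSet", function(x) nrow(x@snps))
setMethod("nIV", "MREstimate", function(x) x@nIV)
setMethod("nIV", "InstrumentSet", function(x) nrow(x@snps))
setMethod("exposureBeta", "HarmonizedSet", function(x) x@betaExposure)
setMethod("exposureSE", "HarmonizedSet", function(x) x@seExposure)
setMethod("outcomeBeta", "HarmonizedSet", function(x) x@betaOutcome)
setMethod("outcomeSE", "HarmonizedSet", function(x) x@seOutcome)
setMethod("snpTable", "HarmonizedSet", function(x) x@snps)
setMethod("snpTable", "SummaryDataset", function(x) x@stats)
setMethod("snpTable", "InstrumentSet", function(x) x@snps)
setMethod("traitName", "SummaryDataset", function(x) x@traitName)

#' Subset a HarmonizedSet by instrument
#'
#' @param x a [HarmonizedSet-class].
#' @param i integer, logical or character (snp id) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@snps$snp)
  new("HarmonizedSet",
      snps = x@snps[i, , drop = FALSE],
      betaExposure = x@betaExposure[i, , drop = FALSE],
      seExposure = x@seExposure[i, , drop = FALSE],
      betaOutcome = x@betaOutcome[i],
      seOutcome = x@seOutcome[i],
      nExposure = x@nExposure, nOutcome = x@nOutcome,
      exposures = x@exposures, outcome = x@outcome)
})

setMethod("show", "SummaryDataset", function(object) {
  cat(sprintf("SummaryDataset '%s' (%s, %s)\n", object@traitName,
              object@traitType, object@ancestry))
  cat(sprintf("  %d variants; total n = %s\n", nrow(object@stats),
              format(object@nTotal, big.mark = ",")))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %d instrument(s), %d exposure(s) -> '%s'\n",
              nrow(object@snps), ncol(object@betaExposure), object@outcome))
  cat("  exposures:", paste(object@exposures, collapse = ", "), "\n")
  prov <- table(object@snps$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(prov), prov),
                             collapse = " "), "\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%-16s nIV=%-4d beta=%8.4f (95%%CI %8.4f to %8.4f)  p=%.3g\n",
              object@method, object@nIV, object@beta, object@ciLow,
              object@ciHigh, object@pvalue))
  if (length(object@extra))
    cat("  extra:", paste(sprintf("%s=%.4g", names(object@extra),
                                  unlist(object@extra)), collapse = "  "),
        "\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf(
    "InstrumentSet: %d instruments (p<%.3g, r2<%.3g, window %g kb)\n",
    nrow(object@snps), object@pThreshold, object@r2Threshold,
    object@windowKb))
  if (is.finite(object@fStat))
    cat(sprintf("  total R2 = %.4g, F = %.2f%s\n", sum(object@r2PerSnp),
                object@fStat,
                if (object@fStat <= 10) " (weak-instrument warning)" else ""))
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport\n")
  cat(sprintf("  Cochran Q = %.3f, df = %d, p = %.3g\n", object@Q,
              object@qDf, object@qP))
  cat(sprintf("  Egger intercept = %.4g (SE %.3g), p = %.3g\n",
              object@eggerIntercept, object@eggerInterceptSE,
              object@eggerInterceptP))
  if (is.finite(object@pressoGlobalP))
    cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
                object@pressoGlobalP, nrow(object@pressoOutliers)))
  s <- object@steiger
  if (length(s))
    cat(sprintf("  Steiger: r2 exposure %.3g vs outcome %.3g, direction %s, p = %.3g\n",
                s$r2Exposure, s$r2Outcome,
                if (isTRUE(s$directionOk)) "ok" else "NOT ok", s$p))
  cat(sprintf("  leave-one-out: %d fits\n", nrow(object@loo)))
})

setMethod("show", "MVMRResult", function(object) {
  cat(sprintf("MVMRResult (%s), %d IVs\n", object@method, object@nIV))
  print(object@estimates, row.names = FALSE)
  cat(sprintf("  adjusted Q = %.2f, df = %d, p = %.3g\n", object@Q,
              object@qDf, object@qP))
  if (is.finite(object@intercept))
    cat(sprintf("  intercept = %.4g, p = %.3g\n", object@intercept,
                object@interceptP))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (product of coefficients)\n")
  cat(sprintf("  total  = %8.4f\n  a (x->m) = %8.4f%s\n  b (m->y) = %8.4f\n",
              object@betaTotal, object@betaXM,
              if (object@mediatorBinary) "  [log-odds]" else "",
              object@betaMY))
  cat(sprintf("  indirect = %8.4f (delta SE %.4f)\n", object@indirect,
              object@seIndirect))
  cat(sprintf("  proportion mediated = %.1f%%\n", object@proportion))
})

setMethod("show", "LdscResult", function(object) {
  cat(sprintf("LdscResult (%d SNPs, %d jackknife blocks)\n", object@nSnps,
              object@nBlocks))
  cat(sprintf("  h2: %.4f (SE %.4f) / %.4f (SE %.4f)\n", object@h2[1],
              object@h2SE[1], object@h2[2], object@h2SE[2]))
  cat(sprintf("  rg = %.4f (SE %.4f), p = %.3g\n", object@rg, object@rgSE,
              object@rgP))
})

setMethod("show", "ConjFdrResult", function(object) {
  cat(sprintf("ConjFdrResult: %d SNPs, %d shared locus/loci at conjFDR < %g\n",
              nrow(object@table), nrow(object@loci), object@threshold))
})
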