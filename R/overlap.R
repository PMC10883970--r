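## Weighted simple regression y ~ 1 + x, weights w, from sufficient
## statistics. Returns per-observation contribution sums so that
## block-jackknife estimates come from subtracting block sums.
.wlsSums <- function(x, y, w) {
  cbind(sw = w, swx = w * x, swy = w * y, swxx = w * x^2, swxy = w * x * y)
}

.slopeFromSums <- function(s) {
  ## s: named vector of summed columns of .wlsSums
  den <- s["sw"] * s["swxx"] - s["swx"]^2
  slope <- (s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / den
  intercept <- (s["swy"] - slope * s["swx"]) / s["sw"]
  c(slope = unname(slope), intercept = unname(intercept))
}

#' Bivariate LD score regression
#'
#' Estimates SNP heritabilities, genetic covariance and the genetic
#' correlation of two traits from genome-wide z-scores and LD scores.
#' Univariate: weighted regression of z^2 on the LD score l_j, whose slope
#' is N*h2/m (intercept free, expected 1 without confounding). Bivariate:
#' regression of z1*z2 on l_j with slope sqrt(n1*n2)*gencov/m; the
#' cross-trait intercept is free and expected 0 for non-overlapping
#' cohorts. Regression weights are 1/l_j (single pass). MHC-region SNPs
#' (chr6: 26-34 Mb) are excluded before fitting. The rg standard error is a
#' delete-one block jackknife over `nBlocks` contiguous SNP blocks.
#'
#' @param z1,z2 data.frames with columns `snp, chrom, pos, z` (and
#'   optionally `n`, `ldscore`), sharing a SNP universe.
#' @param ldScores per-SNP LD scores aligned with `z1$snp`; defaults to the
#'   `ldscore` column of `z1`.
#' @param m number of SNPs the heritability is spread over; defaults to
#'   the shared SNP count before MHC filtering.
#' @param n1,n2 GWAS sample sizes; default to the tables' `n` columns.
#' @param nBlocks jackknife blocks, default 200.
#' @param excludeMhc drop chr6:26-34Mb SNPs first (default TRUE).
#' @return an [LdscResult-class].
#' @export
ldscRg <- function(z1, z2, ldScores = NULL, m = NULL, n1 = NULL, n2 = NULL,
                   nBlocks = 200, excludeMhc = TRUE) {
  shared <- intersect(z1$snp, z2$snp)
  if (!length(shared)) stop("no shared SNPs")
  i1 <- match(shared, z1$snp); i2 <- match(shared, z2$snp)
  ell <- (ldScores %||% z1$ldscore)[i1]
  if (is.null(ell) || any(!is.finite(ell)) || any(ell <= 0))
    stop("positive LD scores required for every shared SNP")
  n1 <- n1 %||% z1$n[i1][1]
  n2 <- n2 %||% z2$n[i2][1]
  if (is.null(n1) || is.null(n2) || is.na(n1) || is.na(n2))
    stop("sample sizes n1/n2 required")
  m <- m %||% length(shared)

  chrom <- z1$chrom[i1]; pos <- z1$pos[i1]
  za <- z1$z[i1]; zb <- z2$z[i2]
  if (excludeMhc) {
    mhc <- chrom == "6" & pos >= 26e6 & pos <= 34e6
    if (any(mhc)) {
      za <- za[!mhc]; zb <- zb[!mhc]; ell <- ell[!mhc]
      chrom <- chrom[!mhc]; pos <- pos[!mhc]
    }
  }
  nSnps <- length(za)
  if (nSnps < 2 * nBlocks)
    stop("fewer than 2 SNPs per jackknife block; reduce nBlocks")

  w <- 1 / ell
  S1 <- .wlsSums(ell, za^2, w)
  S2 <- .wlsSums(ell, zb^2, w)
  S12 <- .wlsSums(ell, za * zb, w)
  tot1 <- colSums(S1); tot2 <- colSums(S2); tot12 <- colSums(S12)

  est <- function(t1, t2, t12) {
    f1 <- .slopeFromSums(t1); f2 <- .slopeFromSums(t2)
    f12 <- .slopeFromSums(t12)
    h2a <- f1["slope"] * m / n1
    h2b <- f2["slope"] * m / n2
    gc <- f12["slope"] * m / sqrt(n1 * n2)
    denom <- sqrt(h2a * h2b)
    rg <- if (is.finite(denom) && denom > 0) gc / denom else NA_real_
    c(h2a = unname(h2a), h2b = unname(h2b), gencov = unname(gc),
      rg = unname(rg), int1 = unname(f1["intercept"]),
      int2 = unname(f2["intercept"]), int12 = unname(f12["intercept"]))
  }
  full <- est(tot1, tot2, tot12)

  ## contiguous blocks in genome order (input is assumed position-sorted
  ## per chromosome; ordering only affects which SNPs share a block)
  blockOf <- ceiling(seq_len(nSnps) / (nSnps / nBlocks))
  bs1 <- rowsum(S1, blockOf); bs2 <- rowsum(S2, blockOf)
  bs12 <- rowsum(S12, blockOf)
  B <- nrow(bs1)
  jack <- matrix(NA_real_, B, 3,
                 dimnames = list(NULL, c("h2a", "h2b", "rg")))
  for (b in seq_len(B)) {
    e <- est(tot1 - bs1[b, ], tot2 - bs2[b, ], tot12 - bs12[b, ])
    jack[b, ] <- e[c("h2a", "h2b", "rg")]
  }
  jse <- apply(jack, 2, function(th) {
    th <- th[is.finite(th)]
    if (length(th) < 2) return(NA_real_)
    sqrt((length(th) - 1) / length(th) * sum((th - mean(th))^2))
  })
  rgSE <- jse["rg"]
  rgP <- if (is.finite(rgSE) && rgSE > 0)
    twoSidedNormalP(full["rg"] / rgSE) else NA_real_
  new("LdscResult", h2 = unname(full[c("h2a", "h2b")]),
      h2SE = unname(jse[c("h2a", "h2b")]), gencov = unname(full["gencov"]),
      rg = unname(full["rg"]), rgSE = unname(rgSE), rgP = rgP,
      intercepts = unname(full[c("int1", "int2", "int12")]),
      nBlocks = as.integer(B), nSnps = as.integer(nSnps))
}

## Count, for each point, how many points have p1 <= p1_j AND p2 <= p2_j
## (self included). O(n log n) via a Fenwick tree over p2 ranks, sweeping
## p1 in ascending order; ties in p1 are inserted as a group before any
## group member is queried so that equal values count each other.
.jointEcdfCounts <- function(p1, p2) {
  n <- length(p1)
  r2 <- rank(p2, ties.method = "max")
  ord <- order(p1)
  tree <- integer(n)
  addBit <- function(i) { while (i <= n) { tree[i] <<- tree[i] + 1L
    i <- i + bitwAnd(i, -i) } }
  queryBit <- function(i) { s <- 0L
    while (i > 0) { s <- s + tree[i]; i <- i - bitwAnd(i, -i) }
    s }
  counts <- integer(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && p1[ord[j + 1]] == p1[ord[i]]) j <- j + 1
    for (k in i:j) addBit(r2[ord[k]])
    for (k in i:j) counts[ord[k]] <- queryBit(r2[ord[k]])
    i <- j + 1
  }
  counts
}

#' Conjunctional FDR for cross-trait shared-locus discovery
#'
#' For each SNP the conditional FDR of trait 1 given trait 2 is estimated
#' empirically as `cFDR(p1|p2) = p1 * F2(p2) / F12(p1, p2)` where `F2` is
#' the empirical CDF of the conditioning p-values and `F12` the joint
#' empirical CDF (capped at 1), and symmetrically for trait 2 given trait
#' 1. The conjunctional FDR is the maximum of the two conditionals. A
#' stratified lookup grid (`nStrata` quantile strata per axis) is made
#' monotone non-decreasing in both arguments by cumulative-max smoothing
#' and returned for diagnostics. SNPs with conjFDR below `locusThreshold`
#' are clumped (when an LD reference is supplied) into shared loci whose
#' lead SNP has the smallest conjFDR.
#'
#' @param p1,p2 data.frames with columns `snp, pvalue` (and optionally
#'   `chrom, pos`), sharing a SNP universe; p-values in (0, 1].
#' @param nStrata strata per axis of the lookup grid, default 10.
#' @param ld optional [LDReference-class] for locus clumping.
#' @param locusThreshold shared-locus cutoff, default 0.05.
#' @param r2Threshold,windowKb clumping parameters for locus definition.
#' @return a [ConjFdrResult-class].
#' @export
conjFdr <- function(p1, p2, nStrata = 10, ld = NULL, locusThreshold = 0.05,
                    r2Threshold = 0.001, windowKb = 10000) {
  shared <- intersect(p1$snp, p2$snp)
  if (!length(shared)) stop("no shared SNPs")
  i1 <- match(shared, p1$snp); i2 <- match(shared, p2$snp)
  q1 <- p1$pvalue[i1]; q2 <- p2$pvalue[i2]
  if (any(q1 <= 0 | q1 > 1 | q2 <= 0 | q2 > 1))
    stop("p-values must lie in (0,1]")
  n <- length(shared)

  F1 <- rank(q1, ties.method = "max") / n
  F2 <- rank(q2, ties.method = "max") / n
  F12 <- .jointEcdfCounts(q1, q2) / n
  cfdr12 <- pmin(1, q1 * F2 / F12)  # FDR of trait 1 given trait 2
  cfdr21 <- pmin(1, q2 * F1 / F12)
  conj <- pmax(cfdr12, cfdr21)

  ## monotone lookup grid on quantile strata, cumulative-max smoothed
  br1 <- unique(stats::quantile(q1, probs = seq_len(nStrata) / nStrata,
                                names = FALSE))
  br2 <- unique(stats::quantile(q2, probs = seq_len(nStrata) / nStrata,
                                names = FALSE))
  gridAt <- function(a, b) {  # cFDR(p1=a | p2=b) at grid nodes
    f2 <- mean(q2 <= b)
    f12 <- mean(q1 <= a & q2 <= b)
    if (f12 == 0) return(NA_real_)
    min(1, a * f2 / f12)
  }
  g12 <- outer(br1, br2, Vectorize(gridAt))
  g21 <- t(outer(br2, br1, Vectorize(function(a, b) {
    f1 <- mean(q1 <= b)
    f12 <- mean(q2 <= a & q1 <= b)
    if (f12 == 0) return(NA_real_)
    min(1, a * f1 / f12)
  })))
  monotone <- function(gmat) {
    gmat[is.na(gmat)] <- 0
    gmat <- apply(gmat, 2, cummax)            # non-decreasing in p1
    t(apply(gmat, 1, cummax))                 # and in p2
  }
  grid <- list(p1Breaks = br1, p2Breaks = br2,
               grid12 = monotone(g12), grid21 = monotone(g21))

  chrom <- if ("chrom" %in% names(p1)) p1$chrom[i1] else NA
  pos <- if ("pos" %in% names(p1)) p1$pos[i1] else NA
  tab <- data.frame(snp = shared, chrom = chrom, pos = pos, p1 = q1,
                    p2 = q2, cfdr12 = cfdr12, cfdr21 = cfdr21,
                    conjfdr = conj, stringsAsFactors = FALSE)

  sig <- tab[tab$conjfdr < locusThreshold, , drop = FALSE]
  if (nrow(sig) && !is.null(ld)) {
    ds <- summaryDataset(data.frame(
      snp = sig$snp, chrom = sig$chrom, pos = sig$pos,
      effect_allele = "A", other_allele = "G", eaf = NA,
      beta = 1, se = 1, pvalue = pmax(sig$conjfdr, 1e-300), n = NA),
      traitName = "conjfdr")
    lead <- tryCatch(
      snpTable(clump(ds, ld, pThreshold = locusThreshold,
                     r2Threshold = r2Threshold, windowKb = windowKb))$snp,
      error = function(e) character())
    loci <- sig[match(lead, sig$snp), c("snp", "chrom", "pos", "conjfdr"),
                drop = FALSE]
  } else {
    loci <- sig[order(sig$conjfdr), c("snp", "chrom", "pos", "conjfdr"),
                drop = FALSE]
  }
  rownames(loci) <- NULL
  new("ConjFdrResult", table = tab, grid = grid, loci = loci,
      threshold = locusThreshold)
}
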