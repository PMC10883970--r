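#' @rdname ldR2
setMethod("ldR2", "BlockLDReference", function(ld, a, b) {
  ia <- match(a, ld@snps$snp)
  ib <- match(b, ld@snps$snp)
  out <- numeric(length(b))
  known <- !is.na(ia) & !is.na(ib)
  if (is.na(ia)) return(out)
  sameBlock <- known & ld@snps$block[ib] == ld@snps$block[ia]
  out[sameBlock] <- ld@blockR[ld@snps$block[ia]]^2
  out[known & ib == ia] <- 1
  out
})

#' @rdname ldR2
setMethod("ldR2", "PairLDReference", function(ld, a, b) {
  vapply(b, function(bb) {
    if (identical(a, bb)) return(1)
    key <- paste(sort(c(a, bb)), collapse = "|")
    get0(key, envir = ld@pairs, ifnotfound = 0)
  }, numeric(1), USE.NAMES = FALSE)
})

setMethod("ldSnpInfo", "BlockLDReference",
          function(ld) ld@snps[c("snp", "chrom", "pos")])
setMethod("ldSnpInfo", "PairLDReference",
          function(ld) ld@snps[c("snp", "chrom", "pos")])

#' Build an LD reference from explicit r^2 pairs
#'
#' @param pairs data.frame `snp_a, snp_b, r2` (symmetric storage not
#'   required); the serialized 3-column TSV form is read with
#'   [data.table::fread()] when `pairs` is a file path.
#' @param snpInfo data.frame `snp, chrom, pos` covering the SNP universe.
#' @return a [PairLDReference-class].
#' @export
ldFromPairs <- function(pairs, snpInfo) {
  if (is.character(pairs))
    pairs <- as.data.frame(data.table::fread(pairs, header = TRUE))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    key <- paste(sort(c(pairs$snp_a[i], pairs$snp_b[i])), collapse = "|")
    assign(key, pairs$r2[i], envir = env)
  }
  new("PairLDReference",
      snps = as.data.frame(snpInfo)[c("snp", "chrom", "pos")], pairs = env)
}

#' Greedy LD clumping of genome-wide-significant variants
#'
#' Selects approximately independent index SNPs: candidates below
#' `pThreshold` are sorted by ascending p (ties broken by chromosome,
#' position, then snp id) and taken greedily; each chosen index removes all
#' remaining candidates on the same chromosome within `windowKb` whose r^2
#' with it reaches `r2Threshold`. SNPs without a chromosome/position in the
#' reference, or on another chromosome, are never removed by a window rule.
#'
#' @param dataset a [SummaryDataset-class] (the exposure GWAS).
#' @param ld an [LDReference-class].
#' @param pThreshold genome-wide significance cutoff, default 5e-8.
#' @param r2Threshold independence cutoff, default 0.001.
#' @param windowKb clumping window in kb (center-to-center), default
#'   10,000 (10 Mb).
#' @return an [InstrumentSet-class] with per-SNP variance explained and the
#'   instrument-strength F statistic when sample sizes are available.
#' @export
clump <- function(dataset, ld, pThreshold = 5e-8, r2Threshold = 0.001,
                  windowKb = 10000) {
  st <- dataset@stats
  cand <- st[st$pvalue < pThreshold, , drop = FALSE]
  if (!nrow(cand))
    stop("no SNP passes the significance threshold p < ", pThreshold)
  info <- ldSnpInfo(ld)
  idx <- match(cand$snp, info$snp)
  chrom <- ifelse(is.na(idx), cand$chrom, info$chrom[idx])
  pos <- ifelse(is.na(idx), cand$pos, info$pos[idx])
  ord <- order(cand$pvalue, chrom, pos, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]

  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    rest <- which(alive)
    if (!length(rest)) break
    inWindow <- !is.na(chrom[rest]) & !is.na(chrom[i]) &
      chrom[rest] == chrom[i] &
      abs(pos[rest] - pos[i]) <= windowKb * 1000
    if (any(inWindow)) {
      r2 <- ldR2(ld, cand$snp[i], cand$snp[rest[inWindow]])
      alive[rest[inWindow][r2 >= r2Threshold]] <- FALSE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  r2PerSnp <- rep(NA_real_, nrow(sel))
  ok <- !is.na(sel$n) & sel$n > 2
  r2PerSnp[ok] <- snpR2(sel$beta[ok], sel$se[ok], sel$n[ok])
  fStat <- NA_real_
  if (all(ok) && nrow(sel) >= 1) {
    N <- dataset@nTotal
    if (is.na(N)) N <- max(sel$n)
    R2 <- sum(r2PerSnp)
    if (R2 > 0 && R2 < 1 && N > nrow(sel) + 1)
      fStat <- fStatistic(R2, N, nrow(sel))
  }
  new("InstrumentSet", snps = sel, pThreshold = pThreshold,
      r2Threshold = r2Threshold, windowKb = windowKb,
      r2PerSnp = r2PerSnp, fStat = as.numeric(fStat))
}

#' Find a proxy SNP in high LD with a missing variant
#'
#' Among SNPs present in `targetDataset`, returns the one with the highest
#' r^2 (strictly greater than `r2Min`) to the query; ties are broken by
#' smallest base-pair distance, then lexicographic id. Returns
#' `NA_character_ when no candidate qualifies — absence is a valid result.
#'
#' @param snpId the missing variant.
#' @param targetDataset [SummaryDataset-class] to search in.
#' @param ld an [LDReference-class].
#' @param r2Min LD floor, default 0.8.
#' @return a snp id or `NA_character_`.
#' @export
findProxy <- function(snpId, targetDataset, ld, r2Min = 0.8) {
  cand <- setdiff(targetDataset@stats$snp, snpId)
  if (!length(cand)) return(NA_character_)
  r2 <- ldR2(ld, snpId, cand)
  ok <- r2 > r2Min
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok]; r2 <- r2[ok]
  info <- ldSnpInfo(ld)
  qpos <- info$pos[match(snpId, info$snp)]
  dist <- abs(info$pos[match(cand, info$snp)] - qpos)
  dist[is.na(dist)] <- Inf
  cand[order(-r2, dist, cand)][1]
}

#' Per-SNP variance in a trait explained by one variant
#'
#' `r2_j = t^2 / (t^2 + n - 2)` with `t = beta/se`; the building block of
#' the Steiger directionality test and of the instrument-strength F
#' statistic. Vectorized.
#'
#' @param beta,se,n effect, standard error and GWAS sample size.
#' @return numeric vector of variance-explained values.
#' @export
snpR2 <- function(beta, se, n) {
  if (any(n <= 2)) stop("sample size must exceed 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument-strength F statistic
#'
#' `F = R2 * (N - k - 1) / (k * (1 - R2))` for total variance explained R2
#' by k instruments in a GWAS of N. Values at or below 10 carry a
#' `weak = TRUE` attribute (conventional weak-instrument threshold).
#'
#' @param R2 total variance explained, in (0,1).
#' @param N exposure GWAS sample size, must exceed k + 1.
#' @param k instrument count, >= 1.
#' @return the F statistic with attribute `weak`.
#' @export
fStatistic <- function(R2, N, k) {
  if (!(R2 > 0 && R2 < 1)) stop("R2 must be in (0,1)")
  if (k < 1) stop("k must be >= 1")
  if (N <= k + 1) stop("N must exceed k + 1")
  f <- R2 * (N - k - 1) / (k * (1 - R2))
  attr(f, "weak") <- f <= 10
  f
}
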