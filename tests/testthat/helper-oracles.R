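## Independent brute-force oracles used by both the unit and the
## end-to-end validation suites.

## Naive greedy clumping over an explicit pairwise r2 matrix.
clumpOracle <- function(st, r2mat, pThr = 5e-8, r2Thr = 0.001,
                        windowKb = 10000) {
  cand <- st[st$pvalue < pThr, ]
  cand <- cand[order(cand$pvalue, cand$chrom, cand$pos, cand$snp), ]
  kept <- character()
  while (nrow(cand)) {
    top <- cand[1, ]
    kept <- c(kept, top$snp)
    drop <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      same <- cand$chrom[i] == top$chrom &&
        abs(cand$pos[i] - top$pos) <= windowKb * 1000
      drop[i] <- i == 1 ||
        (same && r2mat[top$snp, cand$snp[i]] >= r2Thr)
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  kept
}

## Exhaustive double-loop empirical-CDF oracle for the conditional FDR.
cfdrOracle <- function(p1, p2) {
  n <- length(p1)
  c12 <- c21 <- numeric(n)
  for (j in 1:n) {
    F1 <- sum(p1 <= p1[j]) / n
    F2 <- sum(p2 <= p2[j]) / n
    F12 <- sum(p1 <= p1[j] & p2 <= p2[j]) / n
    c12[j] <- min(1, p1[j] * F2 / F12)
    c21[j] <- min(1, p2[j] * F1 / F12)
  }
  list(c12 = c12, c21 = c21)
}
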