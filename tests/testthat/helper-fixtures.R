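## Shared fixture builders. Everything is generated in code; no data files.

## Minimal sumstats data.frame with overridable columns.
makeStats <- function(n = 5, snp = sprintf("rs%03d", seq_len(n)),
                      chrom = "1", pos = seq_len(n) * 1e6,
                      effect_allele = "A", other_allele = "G", eaf = 0.3,
                      beta = 0.1, se = 0.01, pvalue = 1e-10, nGwas = 1e5) {
  data.frame(snp = snp, chrom = chrom, pos = pos,
             effect_allele = rep_len(effect_allele, n),
             other_allele = rep_len(other_allele, n),
             eaf = rep_len(eaf, n), beta = rep_len(beta, n),
             se = rep_len(se, n), pvalue = rep_len(pvalue, n),
             n = rep_len(nGwas, n), stringsAsFactors = FALSE)
}

makeDataset <- function(..., traitName = "trait") {
  summaryDataset(makeStats(...), traitName = traitName)
}

## Harmonized fixture straight from ratio-level quantities.
makeH <- function(gamma, Gamma, seG = 0.01, seO = 0.01, ...) {
  harmonizedSet(betaExposure = gamma, seExposure = rep_len(seG, length(gamma)),
                betaOutcome = Gamma, seOutcome = rep_len(seO, length(gamma)),
                ...)
}

## Simulated study at the default (22-IV, beta = -0.60) conditions.
simStudy <- function(seed, ...) {
  sim <- simulateIvData(mrSimConfig(seed = seed, ...))
  list(h = harmonizePair(sim$exposure, sim$outcome), truth = sim$truth,
       sim = sim)
}

## Independent fixed-effect IVW oracle: weighted least squares of the
## outcome betas on the exposure betas through the origin.
ivwWlsOracle <- function(h) {
  g <- exposureBeta(h)[, 1]
  fit <- lm(outcomeBeta(h) ~ g - 1, weights = 1 / outcomeSE(h)^2)
  list(beta = unname(coef(fit)[1]),
       se = sqrt(1 / sum(g^2 / outcomeSE(h)^2)))
}
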