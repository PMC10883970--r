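#' Configuration for the paired two-sample MR simulator
#'
#' Defaults emulate the study design the package targets: 22 instruments
#' for an exposure GWAS of 446,118 participants against an outcome GWAS of
#' 1,012,240, a true causal effect of -0.60 outcome units per exposure SD,
#' no pleiotropy and no excess heterogeneity. Exposure effects
#' gamma_j ~ N(0.05, 0.015^2) put the instruments firmly in the
#' strong-instrument regime (per-SNP |t| around 30), so that estimator
#' recovery is not confounded with measurement-error attenuation; see the
#' methods vignette for the weak-instrument trade-off.
#'
#' @param nIV number of instruments.
#' @param trueBeta causal effect of exposure on outcome.
#' @param gammaMean,gammaSd distribution of true SNP-exposure effects.
#' @param nExposure,nOutcome GWAS sample sizes (per-SNP SEs are 1/sqrt(n)).
#' @param pleiotropyMode `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (shifted mean) or `"correlated"` (direct effects
#'   correlated 0.5 with the exposure effects, violating InSIDE).
#' @param pleiotropySd,pleiotropyMean distribution of direct effects
#'   alpha_j on the invalid instruments.
#' @param hetSd extra per-IV SD of the outcome effect (heterogeneity).
#' @param propInvalid fraction of instruments receiving pleiotropy.
#' @param palindromicFrac fraction of instruments assigned palindromic
#'   (A/T or G/C) allele pairs, default 0.15 so harmonization filters get
#'   exercised without dominating the data.
#' @param binaryOutcome label the simulated outcome binary (relabels units
#'   only: the effect-size arithmetic is scale-agnostic).
#' @param seed RNG seed.
#' @return a validated [MRSimConfig-class].
#' @export
mrSimConfig <- function(nIV = 22L, trueBeta = -0.60, gammaMean = 0.05,
                        gammaSd = 0.015, nExposure = 446118,
                        nOutcome = 1012240, pleiotropyMode = "none",
                        pleiotropySd = 0, pleiotropyMean = 0, hetSd = 0,
                        propInvalid = 0, palindromicFrac = 0.15,
                        binaryOutcome = FALSE, seed = 1L) {
  new("MRSimConfig", nIV = as.integer(nIV), trueBeta = trueBeta,
      gammaMean = gammaMean, gammaSd = gammaSd, nExposure = nExposure,
      nOutcome = nOutcome, pleiotropyMode = pleiotropyMode,
      pleiotropySd = pleiotropySd, pleiotropyMean = pleiotropyMean,
      hetSd = hetSd, propInvalid = propInvalid,
      palindromicFrac = palindromicFrac, binaryOutcome = binaryOutcome,
      seed = as.integer(seed))
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Instrument-level generative model: for each IV j draw the true exposure
#' effect gamma_j ~ N(gammaMean, gammaSd^2) and observe
#' gammahat_j ~ N(gamma_j, 1/nExposure). A `propInvalid` fraction of IVs
#' receives a direct effect alpha_j according to `pleiotropyMode`; the true
#' outcome effect is Gamma_j = trueBeta * gamma_j + alpha_j + N(0, hetSd^2)
#' and Gammahat_j ~ N(Gamma_j, 1/nOutcome). Alleles are assigned with a
#' configurable palindromic fraction; effect-allele frequencies are shared
#' between the two cohorts. P-values are two-sided normal.
#'
#' The ground truth (which IVs are invalid, the per-IV latent effects and
#' the causal effect) is returned as a sidecar table that the analysis
#' pipeline never sees.
#'
#' @param config an [MRSimConfig-class], see [mrSimConfig()].
#' @return list with elements `exposure` and `outcome`
#'   ([SummaryDataset-class]) and `truth` (data.frame `snp, gamma, alpha,
#'   Gamma, invalid` with attribute `trueBeta`).
#' @export
simulateIvData <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nIV
  gamma <- stats::rnorm(n, config@gammaMean, config@gammaSd)
  seG <- rep(1 / sqrt(config@nExposure), n)
  gammahat <- stats::rnorm(n, gamma, seG)

  nInvalid <- round(config@propInvalid * n)
  invalid <- rep(FALSE, n)
  if (nInvalid > 0) invalid[sample.int(n, nInvalid)] <- TRUE
  alpha <- numeric(n)
  if (any(invalid) && config@pleiotropyMode != "none") {
    m <- sum(invalid)
    alpha[invalid] <- switch(config@pleiotropyMode,
      balanced = stats::rnorm(m, 0, config@pleiotropySd),
      directional = stats::rnorm(m, config@pleiotropyMean,
                                 config@pleiotropySd),
      correlated = {
        ## corr(alpha, gamma) = 0.5 among invalid IVs: violates InSIDE
        zg <- scale(gamma[invalid])[, 1]
        if (!all(is.finite(zg))) zg <- numeric(m)
        config@pleiotropyMean +
          config@pleiotropySd * (0.5 * zg +
                                 sqrt(0.75) * stats::rnorm(m))
      })
  }
  Gamma <- config@trueBeta * gamma + alpha +
    (if (config@hetSd > 0) stats::rnorm(n, 0, config@hetSd) else 0)
  seO <- rep(1 / sqrt(config@nOutcome), n)
  Gammahat <- stats::rnorm(n, Gamma, seO)

  pal <- stats::runif(n) < config@palindromicFrac
  palPairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  npPairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, replace = TRUE),
                                   , drop = FALSE]
  alleles <- matrix("", n, 2)
  if (any(pal)) alleles[pal, ] <- pick(palPairs, sum(pal))
  if (any(!pal)) alleles[!pal, ] <- pick(npPairs, sum(!pal))
  eaf <- stats::runif(n, 0.05, 0.95)

  snp <- sprintf("rs%06d", seq_len(n))
  chrom <- as.character(rep_len(1:22, n))
  pos <- 1e6 + (seq_len(n) %/% 22) * 12e6 + (seq_len(n) %% 22) * 1e4

  mk <- function(beta, se, nGwas, name, type) {
    summaryDataset(data.frame(
      snp = snp, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se,
      pvalue = pmax(twoSidedNormalP(beta / se), 1e-300),
      n = nGwas, stringsAsFactors = FALSE),
      traitName = name, traitType = type, nTotal = nGwas)
  }
  truth <- data.frame(snp = snp, gamma = gamma, alpha = alpha,
                      Gamma = Gamma, invalid = invalid,
                      stringsAsFactors = FALSE)
  attr(truth, "trueBeta") <- config@trueBeta
  list(exposure = mk(gammahat, seG, config@nExposure, "sim_exposure",
                     "quantitative"),
       outcome = mk(Gammahat, seO, config@nOutcome, "sim_outcome",
                    if (config@binaryOutcome) "binary" else "quantitative"),
       truth = truth)
}

#' Configuration for the genome-wide two-trait z-score simulator
#'
#' Defaults give a desk-scale genome: 20,000 SNPs in LD blocks of 50, two
#' cohorts of 50,000, heritabilities 0.3 and a genetic correlation of 0.5.
#' Per-block pairwise LD is drawn uniformly on (0, withinBlockR) so LD
#' scores vary across the genome (a constant LD score would leave the
#' regression slope unidentified).
#'
#' @param mSnps number of SNPs.
#' @param n1,n2 GWAS sample sizes (disjoint cohorts; no overlap term).
#' @param h2_1,h2_2 SNP heritabilities in `[0,1]`.
#' @param rg genetic correlation in `[-1,1]`.
#' @param blockSize SNPs per LD block (last block may be shorter).
#' @param withinBlockR upper bound of the per-block pairwise correlation.
#' @param seed RNG seed.
#' @return a validated [GenomeSimConfig-class].
#' @export
genomeSimConfig <- function(mSnps = 20000L, n1 = 50000, n2 = 50000,
                            h2_1 = 0.3, h2_2 = 0.3, rg = 0.5,
                            blockSize = 50L, withinBlockR = 0.9,
                            seed = 1L) {
  new("GenomeSimConfig", mSnps = as.integer(mSnps), n1 = n1, n2 = n2,
      h2_1 = h2_1, h2_2 = h2_2, rg = rg, blockSize = as.integer(blockSize),
      withinBlockR = withinBlockR, seed = as.integer(seed))
}

#' Simulate genome-wide z-scores for two traits with known rg
#'
#' Draws per-SNP z-score pairs from the bivariate normal implied by the LD
#' score regression expectation (no sample overlap):
#' `E[z1^2] = n1*h2_1*l_j/m + 1`, `E[z2^2] = n2*h2_2*l_j/m + 1` and
#' `E[z1*z2] = sqrt(n1*n2)*rg*sqrt(h2_1*h2_2)*l_j/m`, where the LD score is
#' `l_j = 1 + (blockSize_b - 1)*r_b^2` for the SNP's block. SNPs are placed
#' on chromosomes 1-22 so the MHC filter in [ldscRg()] has coordinates to
#' act on.
#'
#' @param config a [GenomeSimConfig-class], see [genomeSimConfig()].
#' @return list of two data.frames `z1`, `z2`, each with columns
#'   `snp, chrom, pos, z, n, ldscore` on a shared SNP universe.
#' @export
simulateGenomeScan <- function(config) {
  validObject(config)
  if (abs(config@rg) > 1) stop("infeasible covariance: |rg| > 1")
  set.seed(config@seed)
  m <- config@mSnps
  nBlocks <- ceiling(m / config@blockSize)
  blockOf <- rep(seq_len(nBlocks), each = config@blockSize)[seq_len(m)]
  blockSizes <- tabulate(blockOf, nBlocks)
  rBlock <- stats::runif(nBlocks, 0, config@withinBlockR)
  ell <- 1 + (blockSizes[blockOf] - 1) * rBlock[blockOf]^2

  a1 <- 1 + config@n1 * config@h2_1 * ell / m
  a2 <- 1 + config@n2 * config@h2_2 * ell / m
  cc <- sqrt(config@n1 * config@n2) * config@rg *
    sqrt(config@h2_1 * config@h2_2) * ell / m
  u <- stats::rnorm(m); v <- stats::rnorm(m)
  z1 <- sqrt(a1) * u
  z2 <- (cc / sqrt(a1)) * u + sqrt(pmax(a2 - cc^2 / a1, 0)) * v

  perChrom <- ceiling(m / 22)
  chrom <- as.character(((seq_len(m) - 1) %/% perChrom) + 1)
  pos <- ((seq_len(m) - 1) %% perChrom + 1) * 5e4
  snp <- sprintf("rs%07d", seq_len(m))
  mk <- function(z, n) data.frame(snp = snp, chrom = chrom, pos = pos,
                                  z = z, n = n, ldscore = ell,
                                  stringsAsFactors = FALSE)
  list(z1 = mk(z1, config@n1), z2 = mk(z2, config@n2))
}

#' Build a block-structured LD reference panel
#'
#' Emulates the role of an external genotype reference: a symmetric
#' pairwise r^2 lookup with `r^2 = r^2` inside blocks and 0 across blocks.
#' Blocks are laid down sequentially along chromosome 1 with a configurable
#' start-to-start gap so that several blocks fall inside a 10 Mb clumping
#' window.
#'
#' @param nSnps total SNPs.
#' @param blockSize SNPs per block.
#' @param r pairwise within-block correlation (scalar or per-block vector,
#'   recycled).
#' @param blockGapKb start-to-start spacing of consecutive blocks, kb.
#' @param snpSpacingKb spacing of SNPs within a block, kb.
#' @param snpIds optional SNP ids (default `rs000001...`).
#' @return a [BlockLDReference-class].
#' @export
simulateLdReference <- function(nSnps = 50L, blockSize = 5L, r = 0.9,
                                blockGapKb = 2000, snpSpacingKb = 10,
                                snpIds = NULL) {
  nBlocks <- ceiling(nSnps / blockSize)
  blockOf <- rep(seq_len(nBlocks), each = blockSize)[seq_len(nSnps)]
  within <- stats::ave(seq_len(nSnps), blockOf, FUN = seq_along)
  pos <- (blockOf - 1) * blockGapKb * 1000 + (within - 1) *
    snpSpacingKb * 1000 + 1e5
  snp <- snpIds %||% sprintf("rs%06d", seq_len(nSnps))
  new("BlockLDReference",
      snps = data.frame(snp = snp, chrom = "1", pos = pos, block = blockOf,
                        stringsAsFactors = FALSE),
      blockR = rep_len(r, nBlocks))
}
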