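#' Construct a SummaryDataset from a data.frame
#'
#' Validates per-SNP statistics and drops rows violating the invariants
#' (non-positive SE, identical alleles, p-value outside (0,1], out-of-range
#' frequency), with one warning counting the drops per rule.
#'
#' @param stats data.frame with (at least) the canonical columns
#'   `snp, effect_allele, other_allele, beta, se, pvalue`; optional
#'   `chrom, pos, eaf, n` are filled with NA when absent.
#' @param traitName trait label.
#' @param traitType `"quantitative"` (default) or `"binary"` (betas are
#'   log odds ratios).
#' @param nTotal total GWAS sample size; defaults to the maximum per-SNP n.
#' @param ancestry ancestry label, default `"European"`.
#' @return a [SummaryDataset-class].
#' @export
summaryDataset <- function(stats, traitName, traitType = "quantitative",
                           nTotal = NULL, ancestry = "European") {
  stats <- as.data.frame(stats)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se",
                "pvalue")
  miss <- setdiff(required, names(stats))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (opt in c("chrom", "pos", "eaf", "n"))
    if (!opt %in% names(stats)) stats[[opt]] <- NA
  stats <- stats[.SUMSTAT_COLS]
  stats$snp <- as.character(stats$snp)
  stats$effect_allele <- toupper(as.character(stats$effect_allele))
  stats$other_allele <- toupper(as.character(stats$other_allele))
  for (num in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    stats[[num]] <- as.numeric(stats[[num]])

  drop <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    if (any(bad))
      warning(sprintf("dropped %d row(s): %s", sum(bad), why),
              call. = FALSE)
    stats[!bad, , drop = FALSE]
  }
  stats <- drop(is.na(stats$beta) | !is.finite(stats$beta),
                "missing or non-finite beta")
  stats <- drop(!(stats$se > 0), "se not > 0")
  stats <- drop(stats$effect_allele == stats$other_allele,
                "identical alleles")
  stats <- drop(!(stats$pvalue > 0 & stats$pvalue <= 1),
                "p-value outside (0,1]")
  bad.eaf <- !is.na(stats$eaf) & (stats$eaf < 0 | stats$eaf > 1)
  if (any(bad.eaf)) {
    warning(sprintf("dropped %d row(s): eaf outside [0,1]", sum(bad.eaf)),
            call. = FALSE)
    stats <- stats[!bad.eaf, , drop = FALSE]
  }
  dup <- duplicated(stats$snp)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicated snp id(s)", sum(dup)),
            call. = FALSE)
    stats <- stats[!dup, , drop = FALSE]
  }
  if (nrow(stats) == 0) stop("zero usable rows after validation")
  if (is.null(nTotal))
    nTotal <- if (all(is.na(stats$n))) NA_real_ else max(stats$n, na.rm = TRUE)
  new("SummaryDataset", stats = stats, traitName = traitName,
      traitType = traitType, nTotal = nTotal, ancestry = ancestry)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a (possibly gzip-compressed) delimited table, maps its columns to
#' the canonical schema and validates the result. The canonical header is
#' `snp chrom pos effect_allele other_allele eaf beta se pvalue n`; files
#' using other names are mapped through `columnMap`.
#'
#' @param path file path (plain or `.gz`).
#' @param columnMap named character vector or list mapping canonical names
#'   to the file's column names, e.g. `c(snp = "SNP", beta = "BETA")`.
#'   Unmapped canonical names are looked up verbatim (case-insensitively).
#' @param traitName,traitType,nTotal,ancestry trait metadata, see
#'   [summaryDataset()].
#' @param orColumn if TRUE the mapped `beta` column holds odds ratios and
#'   is log-transformed on ingestion (and `traitType` defaults to binary).
#' @return a [SummaryDataset-class].
#' @export
readSumstats <- function(path, columnMap = NULL, traitName = basename(path),
                         traitType = if (orColumn) "binary" else "quantitative",
                         nTotal = NULL, ancestry = "European",
                         orColumn = FALSE) {
  raw <- as.data.frame(data.table::fread(path, header = TRUE,
                                         showProgress = FALSE))
  if (!nrow(raw)) stop("empty file: ", path)
  columnMap <- unlist(columnMap)
  resolve <- function(canon) {
    nm <- if (canon %in% names(columnMap)) columnMap[[canon]] else canon
    hit <- match(tolower(nm), tolower(names(raw)))
    if (is.na(hit)) NA_character_ else names(raw)[hit]
  }
  required <- c("snp", "effect_allele", "other_allele", "beta", "se",
                "pvalue")
  out <- list()
  for (canon in .SUMSTAT_COLS) {
    src <- resolve(canon)
    if (is.na(src)) {
      if (canon %in% required)
        stop("required column '", canon, "' not found in ", path)
      out[[canon]] <- NA
    } else out[[canon]] <- raw[[src]]
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (orColumn) {
    or <- as.numeric(out$beta)
    if (any(or <= 0, na.rm = TRUE))
      warning("non-positive odds ratios set to NA", call. = FALSE)
    or[or <= 0] <- NA
    out$beta <- log(or)
  }
  summaryDataset(out, traitName = traitName, traitType = traitType,
                 nTotal = nTotal, ancestry = ancestry)
}

#' Write a SummaryDataset to the canonical TSV
#' @param x a [SummaryDataset-class].
#' @param path output file path.
#' @export
writeSumstats <- function(x, path) {
  data.table::fwrite(x@stats, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Build a HarmonizedSet directly from aligned effect estimates
#'
#' For data already expressed on a common effect allele (or for simulation
#' fixtures). Vectors are recycled to the instrument count.
#'
#' @param betaExposure,seExposure exposure effects and SEs (vector for one
#'   exposure, matrix for several).
#' @param betaOutcome,seOutcome outcome effects and SEs.
#' @param snp optional instrument ids (default `iv_1, iv_2, ...`).
#' @param nExposure,nOutcome GWAS sample sizes (NA allowed; Steiger then
#'   needs them passed explicitly).
#' @param exposures,outcome trait names.
#' @param chrom,pos,effect_allele,other_allele,eaf optional annotation.
#' @return a [HarmonizedSet-class].
#' @export
harmonizedSet <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                          snp = NULL, nExposure = NA_real_,
                          nOutcome = NA_real_, exposures = NULL,
                          outcome = "outcome", chrom = NA, pos = NA,
                          effect_allele = "A", other_allele = "G",
                          eaf = NA) {
  betaExposure <- as.matrix(betaExposure)
  seExposure <- as.matrix(seExposure)
  n <- nrow(betaExposure)
  K <- ncol(betaExposure)
  exposures <- exposures %||% colnames(betaExposure) %||%
    paste0("exposure", seq_len(K))
  colnames(betaExposure) <- colnames(seExposure) <- exposures
  snp <- snp %||% paste0("iv_", seq_len(n))
  snps <- data.frame(snp = snp, chrom = rep_len(chrom, n),
                     pos = rep_len(pos, n),
                     effect_allele = rep_len(effect_allele, n),
                     other_allele = rep_len(other_allele, n),
                     eaf = rep_len(eaf, n),
                     provenance = "unchanged", stringsAsFactors = FALSE)
  new("HarmonizedSet", snps = snps, betaExposure = betaExposure,
      seExposure = seExposure, betaOutcome = rep_len(betaOutcome, n),
      seOutcome = rep_len(seOutcome, n),
      nExposure = rep_len(nExposure, K), nOutcome = nOutcome,
      exposures = exposures, outcome = outcome)
}

## Align `other` (a stats data.frame) onto `ref`'s allele coding, row-by-row
## for the shared SNP ids. Returns the aligned subset of `other` plus a
## provenance label per kept SNP. Palindromic variants are kept only when
## both frequencies fall on the same unambiguous side of 0.5.
alignAlleles <- function(ref, other, window = 0.42) {
  shared <- intersect(ref$snp, other$snp)
  if (!length(shared)) stop("no shared SNPs between the two datasets")
  r <- ref[match(shared, ref$snp), ]
  o <- other[match(shared, other$snp), ]

  ambiguous <- function(f) is.na(f) | (f > window & f < 1 - window)

  pal <- isPalindromic(r$effect_allele, r$other_allele)
  keep <- rep(TRUE, length(shared))
  provenance <- rep("unchanged", length(shared))
  flip <- rep(FALSE, length(shared))

  oc1 <- complementAllele(o$effect_allele)
  oc2 <- complementAllele(o$other_allele)
  same  <- o$effect_allele == r$effect_allele &
           o$other_allele == r$other_allele
  swap  <- o$effect_allele == r$other_allele &
           o$other_allele == r$effect_allele
  csame <- !is.na(oc1) & !is.na(oc2) & oc1 == r$effect_allele &
           oc2 == r$other_allele
  cswap <- !is.na(oc1) & !is.na(oc2) & oc1 == r$other_allele &
           oc2 == r$effect_allele

  ## non-palindromic: the four rules are mutually exclusive
  np <- !pal
  keep[np & !(same | swap | csame | cswap)] <- FALSE
  flip[np & (swap | cswap)] <- TRUE
  provenance[np & (csame | cswap)] <- "strand_corrected"

  ## palindromic: labels cannot resolve the strand; require both
  ## frequencies unambiguous (outside (window, 1-window)) and on the same
  ## side of 0.5, then keep with the direct orientation
  if (any(pal)) {
    ra <- ambiguous(r$eaf); oa <- ambiguous(o$eaf)
    sameSide <- !ra & !oa & ((r$eaf < 0.5) == (o$eaf < 0.5))
    keep[pal & !sameSide] <- FALSE
    ## allele labels may still be written swapped (T/A vs A/T): treat an
    ## exact label swap as a flip, complement-coded labels as direct
    keep[pal & sameSide & !(same | swap | csame | cswap)] <- FALSE
    flip[pal & sameSide & swap] <- TRUE
  }

  beta <- ifelse(flip, -o$beta, o$beta)
  eaf <- ifelse(flip, 1 - o$eaf, o$eaf)
  provenance[flip & provenance == "unchanged"] <- "flipped"

  data.frame(snp = shared, beta = beta, se = o$se, eaf = eaf,
             pvalue = o$pvalue, n = o$n, keep = keep,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Harmonize an exposure/outcome pair of summary datasets
#'
#' Intersects the two datasets on snp id and aligns the outcome effects to
#' the exposure's effect allele: identical allele pairs are kept, swapped
#' pairs have the outcome beta negated and frequency reflected,
#' complementary-strand codings are relabelled first. Palindromic variants
#' (A/T or G/C) are kept only when both effect-allele frequencies are
#' unambiguous — outside `(palindromeEafWindow, 1 - palindromeEafWindow)` —
#' and fall on the same side of 0.5; in particular any palindromic SNP with
#' either frequency in (0.42, 0.58) (or missing) is removed at the default
#' window. Incompatible allele sets are dropped.
#'
#' @param exposure,outcome [SummaryDataset-class] objects.
#' @param palindromeEafWindow frequency window half-open at 0.42: a
#'   palindromic SNP is ambiguous when its eaf exceeds this value but falls
#'   short of one minus it.
#' @return a single-exposure [HarmonizedSet-class].
#' @export
harmonizePair <- function(exposure, outcome, palindromeEafWindow = 0.42) {
  ex <- exposure@stats
  al <- alignAlleles(ex, outcome@stats, window = palindromeEafWindow)
  al <- al[al$keep, , drop = FALSE]
  if (!nrow(al)) stop("no harmonizable SNPs remain")
  ex <- ex[match(al$snp, ex$snp), ]
  snps <- data.frame(snp = al$snp, chrom = ex$chrom, pos = ex$pos,
                     effect_allele = ex$effect_allele,
                     other_allele = ex$other_allele, eaf = ex$eaf,
                     provenance = al$provenance, stringsAsFactors = FALSE)
  nexp <- exposure@nTotal
  if (is.na(nexp)) nexp <- suppressWarnings(max(ex$n, na.rm = TRUE))
  nout <- outcome@nTotal
  if (is.na(nout)) nout <- suppressWarnings(max(al$n, na.rm = TRUE))
  new("HarmonizedSet", snps = snps,
      betaExposure = matrix(ex$beta, ncol = 1,
                            dimnames = list(NULL, exposure@traitName)),
      seExposure = matrix(ex$se, ncol = 1,
                          dimnames = list(NULL, exposure@traitName)),
      betaOutcome = al$beta, seOutcome = al$se,
      nExposure = nexp, nOutcome = nout,
      exposures = exposure@traitName, outcome = outcome@traitName)
}

#' Harmonize several exposures and one outcome into a multi-exposure set
#'
#' Builds the instrument union across exposures (the ids in `instruments`,
#' by default every SNP of every exposure), restricts it to SNPs present in
#' every exposure dataset and in the outcome, and aligns all effects to the
#' first exposure's allele coding using the same rules as
#' [harmonizePair()]. SNPs missing from any dataset are dropped with a
#' message.
#'
#' @param exposures list of >= 2 [SummaryDataset-class] objects.
#' @param outcome a [SummaryDataset-class].
#' @param instruments optional character vector (or list of vectors) of
#'   instrument snp ids to union; defaults to all SNPs of all exposures.
#' @param palindromeEafWindow see [harmonizePair()].
#' @return a multi-exposure [HarmonizedSet-class].
#' @export
harmonizeMulti <- function(exposures, outcome, instruments = NULL,
                           palindromeEafWindow = 0.42) {
  if (length(exposures) < 2) stop("need >= 2 exposure datasets")
  cand <- if (is.null(instruments))
    unique(unlist(lapply(exposures, function(d) d@stats$snp)))
  else unique(unlist(instruments))
  present <- Reduce(intersect,
                    c(lapply(exposures, function(d) d@stats$snp),
                      list(outcome@stats$snp)))
  dropped <- setdiff(cand, present)
  if (length(dropped))
    message(length(dropped),
            " instrument(s) absent from at least one dataset; dropped")
  cand <- intersect(cand, present)
  if (!length(cand)) stop("no instruments present in every dataset")

  ref <- exposures[[1]]@stats
  ref <- ref[match(cand, ref$snp), ]
  K <- length(exposures)
  betaE <- seE <- matrix(NA_real_, nrow(ref), K)
  colnames(betaE) <- colnames(seE) <-
    vapply(exposures, function(d) d@traitName, character(1))
  betaE[, 1] <- ref$beta; seE[, 1] <- ref$se
  keep <- rep(TRUE, nrow(ref))
  prov <- rep("unchanged", nrow(ref))
  for (k in seq_len(K)[-1]) {
    al <- alignAlleles(ref, exposures[[k]]@stats,
                       window = palindromeEafWindow)
    al <- al[match(ref$snp, al$snp), ]
    keep <- keep & al$keep
    betaE[, k] <- al$beta; seE[, k] <- al$se
    prov[al$provenance != "unchanged" & prov == "unchanged"] <-
      al$provenance[al$provenance != "unchanged" & prov == "unchanged"]
  }
  alO <- alignAlleles(ref, outcome@stats, window = palindromeEafWindow)
  alO <- alO[match(ref$snp, alO$snp), ]
  keep <- keep & alO$keep
  prov[alO$provenance != "unchanged" & prov == "unchanged"] <-
    alO$provenance[alO$provenance != "unchanged" & prov == "unchanged"]
  if (!any(keep)) stop("no harmonizable SNPs remain")

  nE <- vapply(exposures, function(d) {
    n <- d@nTotal
    if (is.na(n)) n <- suppressWarnings(max(d@stats$n, na.rm = TRUE))
    n
  }, numeric(1))
  nO <- outcome@nTotal
  if (is.na(nO)) nO <- suppressWarnings(max(outcome@stats$n, na.rm = TRUE))

  snps <- data.frame(snp = ref$snp, chrom = ref$chrom, pos = ref$pos,
                     effect_allele = ref$effect_allele,
                     other_allele = ref$other_allele, eaf = ref$eaf,
                     provenance = prov, stringsAsFactors = FALSE)
  new("HarmonizedSet",
      snps = snps[keep, , drop = FALSE],
      betaExposure = betaE[keep, , drop = FALSE],
      seExposure = seE[keep, , drop = FALSE],
      betaOutcome = alO$beta[keep], seOutcome = alO$se[keep],
      nExposure = nE, nOutcome = nO,
      exposures = colnames(betaE), outcome = outcome@traitName)
}
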