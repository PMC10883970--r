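test_that("readSumstats maps columns, validates rows and log-transforms ORs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                   A1 = c("a", "C", "G", "T"), A2 = c("g", "T", "G", "C"),
                   OR = c(1.5, 0.8, 1.1, 2.0),
                   SE = c(0.1, 0.2, 0.1, 0), P = c(0.01, 0.5, 0.2, 0.3),
                   N = 1000)
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  map <- c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
           beta = "OR", se = "SE", pvalue = "P", n = "N")
  ## rs3 has identical alleles, rs4 has se = 0: both dropped with warnings
  ds <- suppressWarnings(
    readSumstats(f, columnMap = map, orColumn = TRUE, traitName = "t"))
  st <- snpTable(ds)
  expect_equal(st$snp, c("rs1", "rs2"))
  expect_equal(st$beta, log(c(1.5, 0.8)))      # log-transform oracle
  expect_equal(st$effect_allele, c("A", "C"))  # uppercased
  w2 <- capture_warnings(readSumstats(f, columnMap = map, orColumn = TRUE))
  expect_match(w2, "dropped", all = FALSE)
  expect_error(readSumstats(f, columnMap = map[-4]), "required column")
})

test_that("row validation drops se<=0 and out-of-range p with counted warnings", {
  st <- makeStats(n = 4)
  st$se[2] <- 0
  st$pvalue[3] <- 0
  w <- capture_warnings(ds <- summaryDataset(st, "t"))
  expect_match(w, "dropped 1 row", all = FALSE)
  expect_equal(nrow(snpTable(ds)), 2)
  st0 <- makeStats(n = 1); st0$se <- -1
  expect_error(suppressWarnings(summaryDataset(st0, "t")), "zero usable")
})

test_that("harmonizePair applies identity, swap and strand-complement rules", {
  exp <- makeDataset(n = 3, beta = 0.1, eaf = 0.3)
  out <- makeStats(n = 3, beta = 0.05, eaf = 0.3)
  ## rs002: alleles written swapped; rs003: complementary strand, swapped
  out$effect_allele <- c("A", "G", "C")
  out$other_allele <- c("G", "A", "T")
  out$eaf[2] <- 0.3
  h <- harmonizePair(exp, summaryDataset(out, "o"))
  expect_equal(nIV(h), 3)
  expect_equal(outcomeBeta(h), c(0.05, -0.05, -0.05))
  expect_equal(snpTable(h)$provenance,
               c("unchanged", "flipped", "strand_corrected"))
})

test_that("palindromic SNPs with ambiguous or opposite-side frequencies are removed", {
  exp <- makeDataset(n = 4, effect_allele = c("A", "A", "C", "A"),
                     other_allele = c("T", "T", "G", "G"),
                     eaf = c(0.50, 0.30, 0.70, 0.30))
  out <- makeStats(n = 4, effect_allele = c("A", "A", "C", "A"),
                   other_allele = c("T", "T", "G", "G"),
                   eaf = c(0.50, 0.30, 0.25, 0.30), beta = 0.05)
  h <- harmonizePair(exp, summaryDataset(out, "o"))
  ## rs001 ambiguous (eaf 0.5), rs003 opposite sides: dropped;
  ## rs002 palindromic but unambiguous same side: kept; rs004 ordinary
  expect_setequal(snpTable(h)$snp, c("rs002", "rs004"))
  ## boundary: eaf just inside the (0.42, 0.58) window is removed
  exp2 <- makeDataset(n = 1, effect_allele = "A", other_allele = "T",
                      eaf = 0.43)
  out2 <- summaryDataset(makeStats(n = 1, effect_allele = "A",
                                   other_allele = "T", eaf = 0.43), "o")
  expect_error(harmonizePair(exp2, out2), "no harmonizable")
})

test_that("no palindromic SNP with intermediate frequency survives harmonization", {
  set.seed(42)
  for (i in 1:20) {
    sim <- simulateIvData(mrSimConfig(nIV = 40, palindromicFrac = 0.5,
                                      seed = i))
    ## scatter frequencies into the ambiguous window
    e <- sim$exposure; o <- sim$outcome
    amb <- runif(40) < 0.5
    e@stats$eaf[amb] <- o@stats$eaf[amb] <- runif(sum(amb), 0.43, 0.57)
    h <- harmonizePair(e, o)
    st <- snpTable(h)
    pal <- with(st, (effect_allele == "A" & other_allele == "T") |
                    (effect_allele == "T" & other_allele == "A") |
                    (effect_allele == "C" & other_allele == "G") |
                    (effect_allele == "G" & other_allele == "C"))
    expect_false(any(pal & st$eaf > 0.42 & st$eaf < 0.58))
  }
})

test_that("harmonization is idempotent and sign-equivariant", {
  s <- simStudy(3)
  st <- snpTable(s$h)
  ## rebuild both sides from the harmonized table and re-harmonize
  exp2 <- summaryDataset(
    data.frame(st[c("snp", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf")], beta = exposureBeta(s$h)[, 1],
               se = exposureSE(s$h)[, 1], pvalue = 0.5, n = 1e5), "e")
  out2 <- summaryDataset(
    data.frame(st[c("snp", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf")], beta = outcomeBeta(s$h), se = outcomeSE(s$h),
               pvalue = 0.5, n = 1e5), "o")
  h2 <- harmonizePair(exp2, out2)
  expect_equal(snpTable(h2)$snp, st$snp)
  expect_equal(exposureBeta(h2)[, 1], exposureBeta(s$h)[, 1])
  expect_equal(outcomeBeta(h2), outcomeBeta(s$h))

  ## negating the exposure betas and swapping its allele labels leaves the
  ## causal content unchanged: outcome betas flip with the new coding
  exp3 <- exp2
  exp3@stats$beta <- -exp3@stats$beta
  tmp <- exp3@stats$effect_allele
  exp3@stats$effect_allele <- exp3@stats$other_allele
  exp3@stats$other_allele <- tmp
  exp3@stats$eaf <- 1 - exp3@stats$eaf
  h3 <- harmonizePair(exp3, out2)
  shared <- intersect(snpTable(h3)$snp, st$snp)
  i3 <- match(shared, snpTable(h3)$snp); i2 <- match(shared, st$snp)
  expect_equal(exposureBeta(h3)[i3, 1], -exposureBeta(h2)[i2, 1])
  expect_equal(outcomeBeta(h3)[i3], -outcomeBeta(h2)[i2])
  expect_equal(waldRatios(h3)$ratio[i3], waldRatios(h2)$ratio[i2])
})

test_that("harmonizeMulti restricts the union to SNPs present everywhere", {
  e1 <- makeDataset(n = 5, traitName = "e1", beta = 0.1)
  e2 <- makeDataset(n = 5, traitName = "e2", beta = 0.2)
  out <- makeDataset(n = 5, traitName = "o", beta = 0.01)
  mh <- harmonizeMulti(list(e1, e2), out)
  expect_equal(nIV(mh), 5)
  expect_equal(ncol(exposureBeta(mh)), 2)
  ## drop one SNP from e2: excluded with a message
  e2b <- e2; e2b@stats <- e2b@stats[-3, ]
  expect_message(mh2 <- harmonizeMulti(list(e1, e2b), out), "dropped")
  expect_equal(nIV(mh2), 4)
  expect_false("rs003" %in% snpTable(mh2)$snp)
})
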