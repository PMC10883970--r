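#' Assemble a study configuration
#'
#' Gathers every tunable of the workflow — instrument-selection thresholds
#' (genome-wide significance 5e-8, clumping r^2 0.001, 10 Mb window, proxy
#' r^2 0.8), the palindrome frequency window 0.42, MR-PRESSO simulation
#' count 1000 and outlier p 0.05 — with the datasets to analyse. Datasets
#' may be given as [SummaryDataset-class] objects or as paths (with
#' optional per-file `columnMap`/`orColumn` entries in `readArgs`).
#'
#' @param exposures named list of exposure datasets (or paths).
#' @param outcome outcome dataset (or path).
#' @param mediators optional named list of mediator datasets (or paths).
#' @param ld optional [LDReference-class] for clumping and proxy search.
#' @param pThreshold,r2Threshold,windowKb clumping parameters.
#' @param proxyR2 proxy-search LD floor.
#' @param palindromeEafWindow harmonization frequency window.
#' @param pressoNSim,pressoOutlierP MR-PRESSO parameters.
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir output directory (created on run).
#' @param readArgs named list of extra [readSumstats()] arguments per
#'   dataset name.
#' @return a `StudyConfig` list (class `"studyConfig"`).
#' @export
studyConfig <- function(exposures, outcome, mediators = NULL, ld = NULL,
                        pThreshold = 5e-8, r2Threshold = 0.001,
                        windowKb = 10000, proxyR2 = 0.8,
                        palindromeEafWindow = 0.42, pressoNSim = 1000,
                        pressoOutlierP = 0.05, nBoot = 1000, seed = 1,
                        outDir = tempfile("somnimr_study_"),
                        readArgs = list()) {
  stopifnot(pThreshold > 0, pThreshold <= 1, r2Threshold >= 0,
            r2Threshold <= 1, windowKb > 0, proxyR2 >= 0, proxyR2 <= 1,
            palindromeEafWindow >= 0, palindromeEafWindow <= 0.5,
            pressoNSim >= 0, pressoOutlierP > 0, pressoOutlierP <= 1)
  if (is(exposures, "SummaryDataset")) exposures <- list(exposures)
  structure(list(exposures = exposures, outcome = outcome,
                 mediators = mediators, ld = ld, pThreshold = pThreshold,
                 r2Threshold = r2Threshold, windowKb = windowKb,
                 proxyR2 = proxyR2,
                 palindromeEafWindow = palindromeEafWindow,
                 pressoNSim = pressoNSim, pressoOutlierP = pressoOutlierP,
                 nBoot = nBoot, seed = seed, outDir = outDir,
                 readArgs = readArgs),
            class = "studyConfig")
}

#' Load a study configuration from YAML
#'
#' File-based counterpart of [studyConfig()]: dataset entries are paths
#' with optional `column_map`/`or_column`/`trait_name`/`n_total` fields;
#' thresholds default as in [studyConfig()].
#'
#' @param path YAML file.
#' @return a `studyConfig` list.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  loadOne <- function(e) {
    if (is.character(e)) e <- list(path = e)
    readSumstats(e$path, columnMap = e$column_map,
                 traitName = e$trait_name %||% basename(e$path),
                 nTotal = e$n_total,
                 orColumn = isTRUE(e$or_column))
  }
  exposures <- lapply(y$exposures, loadOne)
  names(exposures) <- vapply(exposures, traitName, character(1))
  mediators <- if (length(y$mediators)) {
    m <- lapply(y$mediators, loadOne)
    names(m) <- vapply(m, traitName, character(1))
    m
  }
  ld <- if (!is.null(y$ld))
    ldFromPairs(y$ld$pairs, utils::read.delim(y$ld$snp_info))
  th <- y$thresholds %||% list()
  studyConfig(exposures = exposures, outcome = loadOne(y$outcome),
              mediators = mediators, ld = ld,
              pThreshold = th[["p"]] %||% 5e-8,
              r2Threshold = th[["r2"]] %||% 0.001,
              windowKb = th[["window_kb"]] %||% 10000,
              proxyR2 = th[["proxy_r2"]] %||% 0.8,
              palindromeEafWindow = th[["palindrome_window"]] %||% 0.42,
              pressoNSim = th[["presso_nsim"]] %||% 1000,
              pressoOutlierP = th[["presso_outlier_p"]] %||% 0.05,
              nBoot = th[["n_boot"]] %||% 1000,
              seed = y[["seed"]] %||% 1,
              outDir = y[["out_dir"]] %||% tempfile("somnimr_study_"))
}

## One univariable exposure -> outcome analysis: clump, proxy fill,
## harmonize, PRESSO filter, five estimators + sensitivity suite.
runUnivariable <- function(exposure, outcome, cfg, seedTag) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(cfg$ld)) {
    iv <- clump(exposure, cfg$ld, cfg$pThreshold, cfg$r2Threshold,
                cfg$windowKb)
    ivSnps <- snpTable(iv)$snp
    note("clump: %d instrument(s) retained of %d candidates",
         length(ivSnps), sum(snpTable(exposure)$pvalue < cfg$pThreshold))
  } else {
    st <- snpTable(exposure)
    ivSnps <- st$snp[st$pvalue < cfg$pThreshold]
    iv <- NULL
    note("no LD reference: %d significant SNP(s) taken as independent",
         length(ivSnps))
    if (!length(ivSnps)) stop("no SNP passes the significance threshold")
  }

  ## proxy fill for instruments missing from the outcome
  missing <- setdiff(ivSnps, snpTable(outcome)$snp)
  proxied <- character()
  if (length(missing) && !is.null(cfg$ld)) {
    for (s in missing) {
      pr <- findProxy(s, outcome, cfg$ld, cfg$proxyR2)
      if (!is.na(pr) && pr %in% snpTable(exposure)$snp &&
          !pr %in% ivSnps) {
        ivSnps <- c(setdiff(ivSnps, s), pr)
        proxied <- c(proxied, pr)
        note("proxy: %s replaced by %s", s, pr)
      } else note("dropped %s: absent from outcome, no usable proxy", s)
    }
  } else if (length(missing)) {
    note("dropped %d instrument(s) absent from outcome (no LD reference)",
         length(missing))
  }

  exIv <- exposure
  exIv@stats <- exIv@stats[exIv@stats$snp %in% ivSnps, , drop = FALSE]
  h <- harmonizePair(exIv, outcome, cfg$palindromeEafWindow)
  h@snps$provenance[h@snps$snp %in% proxied] <- "proxied"
  dropped <- setdiff(ivSnps, snpTable(h)$snp)
  if (length(dropped))
    note("harmonization dropped: %s", paste(dropped, collapse = ", "))

  presso <- NULL
  if (cfg$pressoNSim > 0 && nIV(h) >= 4) {
    presso <- mrPresso(h, nSim = cfg$pressoNSim,
                       outlierP = cfg$pressoOutlierP,
                       seed = subSeed(cfg$seed, paste0(seedTag, "_presso")))
    if (nrow(presso$outliers) && nIV(presso$filtered) >= 3) {
      note("MR-PRESSO removed outlier(s): %s",
           paste(presso$outliers$snp, collapse = ", "))
      h <- presso$filtered
    } else if (nrow(presso$outliers)) {
      note("MR-PRESSO flagged %d of %d instruments; too few would remain, none removed",
           nrow(presso$outliers), nIV(h))
    }
  }

  est <- mrAllMethods(h, seed = subSeed(cfg$seed, seedTag),
                      nBoot = cfg$nBoot)
  sens <- sensitivitySuite(h, pressoNSim = 0,
                           seed = subSeed(cfg$seed, seedTag))
  if (!is.null(presso)) {
    sens@pressoGlobalP <- presso$globalP
    sens@pressoOutliers <- presso$outliers
  }
  list(h = h, instruments = iv, estimates = est, sensitivity = sens,
       log = log)
}

#' Run the full study workflow
#'
#' Executes, per exposure: LD clumping, proxy substitution for instruments
#' missing from the outcome, allele harmonization, MR-PRESSO outlier
#' filtering, the five univariable estimators and the sensitivity suite.
#' With two or more exposures a multivariable MR over the instrument union
#' follows; with mediators, the two-step mediation analysis (exposure ->
#' mediator, mediator -> outcome, product of coefficients). Writes
#' `table1.tsv` (univariable), `table2.tsv` (MVMR), `table3.tsv`
#' (mediation), `sensitivity.json`, `manifest.json`, a per-SNP drop log
#' and SVG diagnostic plots into `config$outDir`.
#'
#' @param config a `studyConfig` list from [studyConfig()] or
#'   [readStudyConfig()].
#' @return invisibly, a list with all in-memory results (`univariable`,
#'   `mvmr`, `mediation`, `paths`).
#' @export
runStudy <- function(config) {
  cfg <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(cfg$exposures)))
    names(cfg$exposures) <- vapply(cfg$exposures, traitName, character(1))

  stage <- "univariable"
  uni <- list()
  result <- tryCatch({
    for (nm in names(cfg$exposures))
      uni[[nm]] <- runUnivariable(cfg$exposures[[nm]], cfg$outcome, cfg,
                                  seedTag = paste0("uni_", nm))

    table1 <- do.call(rbind, lapply(names(uni), function(nm)
      cbind(exposure = nm, uni[[nm]]$estimates)))

    mv <- NULL
    table2 <- NULL
    if (length(cfg$exposures) >= 2) {
      stage <- "mvmr"
      ivUnion <- lapply(uni, function(u) snpTable(u$h)$snp)
      mh <- harmonizeMulti(cfg$exposures, cfg$outcome,
                           instruments = ivUnion,
                           palindromeEafWindow = cfg$palindromeEafWindow)
      mvIvw <- mvmrFit(mh, "ivw")
      mvEgger <- mvmrFit(mh, "egger")
      ## IVW is primary unless the Egger intercept signals pleiotropy
      primary <- if (is.finite(mvEgger@interceptP) &&
                     mvEgger@interceptP < 0.05) "egger" else "ivw"
      mv <- list(ivw = mvIvw, egger = mvEgger, primary = primary)
      table2 <- rbind(cbind(method = "ivw", mvIvw@estimates),
                      cbind(method = "egger", mvEgger@estimates))
    }

    med <- NULL
    table3 <- NULL
    if (length(cfg$mediators)) {
      stage <- "mediation"
      med <- list()
      rows <- list()
      firstExp <- cfg$exposures[[1]]
      total <- uni[[1]]$estimates
      totalIvw <- newMREstimate(
        "ivw_total", total$n_iv[1],
        total$beta[grepl("ivw", total$method)][1],
        total$se[grepl("ivw", total$method)][1])
      for (mm in names(cfg$mediators)) {
        mdat <- cfg$mediators[[mm]]
        step1 <- runUnivariable(firstExp, mdat, cfg,
                                seedTag = paste0("med1_", mm))
        step2 <- runUnivariable(mdat, cfg$outcome, cfg,
                                seedTag = paste0("med2_", mm))
        grabIvw <- function(u) {
          r <- u$estimates[grepl("ivw", u$estimates$method), ][1, ]
          newMREstimate(r$method, r$n_iv, r$beta, r$se)
        }
        mr <- mediate(grabIvw(step1), grabIvw(step2), totalIvw,
                      mediatorBinary = mdat@traitType == "binary")
        med[[mm]] <- list(step1 = step1, step2 = step2, result = mr)
        rows[[mm]] <- data.frame(
          mediator = mm, beta_total = mr@betaTotal, beta_xm = mr@betaXM,
          beta_my = mr@betaMY, indirect = mr@indirect,
          se_indirect = mr@seIndirect, proportion_pct = mr@proportion,
          stringsAsFactors = FALSE)
      }
      table3 <- do.call(rbind, rows)
    }

    stage <- "output"
    paths <- list(table1 = file.path(cfg$outDir, "table1.tsv"))
    data.table::fwrite(table1, paths$table1, sep = "\t", quote = FALSE)
    if (!is.null(table2)) {
      paths$table2 <- file.path(cfg$outDir, "table2.tsv")
      data.table::fwrite(table2, paths$table2, sep = "\t", quote = FALSE)
    }
    if (!is.null(table3)) {
      paths$table3 <- file.path(cfg$outDir, "table3.tsv")
      data.table::fwrite(table3, paths$table3, sep = "\t", quote = FALSE)
    }

    sensJson <- lapply(uni, function(u) {
      s <- u$sensitivity
      list(Q = s@Q, q_df = s@qDf, q_p = s@qP,
           egger_intercept = s@eggerIntercept,
           egger_intercept_p = s@eggerInterceptP,
           presso_global_p = s@pressoGlobalP,
           presso_outliers = s@pressoOutliers$snp,
           steiger = s@steiger,
           loo = s@loo)
    })
    paths$sensitivity <- file.path(cfg$outDir, "sensitivity.json")
    jsonlite::write_json(sensJson, paths$sensitivity, auto_unbox = TRUE,
                         digits = NA, na = "null")

    manifest <- list(
      package = "somnimr",
      version = as.character(utils::packageVersion("somnimr")),
      seed = cfg$seed,
      thresholds = cfg[c("pThreshold", "r2Threshold", "windowKb",
                         "proxyR2", "palindromeEafWindow", "pressoNSim",
                         "pressoOutlierP", "nBoot")],
      exposures = names(cfg$exposures),
      outcome = traitName(cfg$outcome),
      mediators = names(cfg$mediators),
      mvmr_primary = if (!is.null(mv)) mv$primary,
      drop_log = lapply(uni, `[[`, "log"))
    paths$manifest <- file.path(cfg$outDir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, na = "null")

    ## diagnostic plots for the first exposure (skipped without cairo)
    u1 <- uni[[1]]
    plotScatter(u1$h, u1$estimates,
                file.path(cfg$outDir, "scatter.svg"),
                interceptEgger = u1$sensitivity@eggerIntercept)
    plotForest(u1$h, file.path(cfg$outDir, "forest.svg"))
    plotLeaveOneOut(u1$sensitivity@loo,
                    file.path(cfg$outDir, "leave_one_out.svg"))

    list(univariable = uni, mvmr = mv, mediation = med, paths = paths,
         table1 = table1, table2 = table2, table3 = table3)
  }, error = function(e) {
    stop(sprintf("study aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
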