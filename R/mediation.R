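#' Two-step MR mediation by the product of coefficients
#'
#' Combines three MR estimates — exposure on mediator (step 1), mediator on
#' outcome (step 2) and the total exposure-on-outcome effect — into an
#' indirect (mediated) effect `beta_xm * beta_my` and the proportion of the
#' total effect mediated, `100 * indirect / total` (percent). For a binary
#' mediator both step betas must already be on the log-odds scale (odds
#' ratios are log-transformed at ingestion, see [readSumstats()]); the
#' `mediatorBinary` flag records that scale. The indirect-effect SE is a
#' delta-method extension, `sqrt(bxm^2 se_my^2 + bmy^2 se_xm^2)`; the
#' proportion is flagged undefined when the total effect is zero.
#'
#' @param step1 [MREstimate-class] (or list with `beta`, `se`) for
#'   exposure -> mediator.
#' @param step2 [MREstimate-class] for mediator -> outcome.
#' @param total [MREstimate-class] for exposure -> outcome.
#' @param mediatorBinary is the mediator binary (step-1 beta a log-OR)?
#' @return a [MediationResult-class].
#' @export
mediate <- function(step1, step2, total, mediatorBinary = FALSE) {
  grab <- function(x) {
    if (is(x, "MREstimate")) list(beta = x@beta, se = x@se)
    else list(beta = x$beta, se = x$se %||% NA_real_)
  }
  s1 <- grab(step1); s2 <- grab(step2); tt <- grab(total)
  indirect <- s1$beta * s2$beta
  seInd <- sqrt(s1$beta^2 * s2$se^2 + s2$beta^2 * s1$se^2)
  if (tt$beta == 0) {
    warning("total effect is zero: proportion mediated undefined",
            call. = FALSE)
    prop <- NA_real_
  } else prop <- 100 * indirect / tt$beta
  keepEst <- function(x) if (is(x, "MREstimate")) x else
    newMREstimate("supplied", 0L, x$beta, if (is.na(x$se)) 1 else x$se)
  new("MediationResult", betaTotal = tt$beta, betaXM = s1$beta,
      betaMY = s2$beta, indirect = indirect, seIndirect = seInd,
      proportion = prop, mediatorBinary = mediatorBinary,
      steps = list(step1 = keepEst(step1), step2 = keepEst(step2),
                   total = keepEst(total)))
}
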