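## Base-graphics diagnostic plots written as SVG (silently skipped when the
## cairo SVG device is unavailable).

svgDevice <- function(path, width = 6, height = 5) {
  ok <- tryCatch({ grDevices::svg(path, width = width, height = height)
    TRUE }, error = function(e) FALSE)
  ok
}

#' Scatter plot of instrument effects with method fit lines
#'
#' @param h a single-exposure [HarmonizedSet-class].
#' @param estimates data.frame from [mrAllMethods()] (needs `method`,
#'   `beta`; Egger rows may carry an intercept attribute).
#' @param path output SVG path.
#' @param interceptEgger intercept of the Egger fit (0 for the others).
#' @return the path, invisibly (NULL when no SVG device is available).
#' @export
plotScatter <- function(h, estimates, path, interceptEgger = 0) {
  if (!svgDevice(path)) return(invisible(NULL))
  on.exit(grDevices::dev.off())
  g <- h@betaExposure[, 1]; G <- h@betaOutcome
  graphics::plot(g, G, pch = 19, col = "grey30",
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome")
  graphics::arrows(g, G - h@seOutcome, g, G + h@seOutcome, angle = 90,
                   code = 3, length = 0.02, col = "grey70")
  cols <- grDevices::hcl.colors(nrow(estimates), "Dark 3")
  for (i in seq_len(nrow(estimates))) {
    a <- if (grepl("egger", estimates$method[i])) interceptEgger else 0
    graphics::abline(a = a, b = estimates$beta[i], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = estimates$method, col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(path)
}

#' Forest plot of per-instrument Wald ratios
#' @param h a single-exposure [HarmonizedSet-class].
#' @param path output SVG path.
#' @export
plotForest <- function(h, path) {
  if (!svgDevice(path, height = 0.25 * nIV(h) + 2)) return(invisible(NULL))
  on.exit(grDevices::dev.off())
  wr <- waldRatios(h)
  ord <- order(wr$ratio)
  y <- seq_along(ord)
  graphics::plot(wr$ratio[ord], y, pch = 19, yaxt = "n",
                 xlim = range(wr$ratio + 2 * wr$se, wr$ratio - 2 * wr$se),
                 xlab = "per-IV causal estimate", ylab = "")
  graphics::segments(wr$ratio[ord] - 1.96 * wr$se[ord], y,
                     wr$ratio[ord] + 1.96 * wr$se[ord], y)
  graphics::axis(2, at = y, labels = wr$snp[ord], las = 1, cex.axis = 0.6)
  graphics::abline(v = 0, lty = 2)
  invisible(path)
}

#' Forest plot of the leave-one-out series
#' @param loo data.frame from [leaveOneOut()].
#' @param path output SVG path.
#' @export
plotLeaveOneOut <- function(loo, path) {
  if (!svgDevice(path, height = 0.25 * nrow(loo) + 2))
    return(invisible(NULL))
  on.exit(grDevices::dev.off())
  y <- seq_len(nrow(loo))
  graphics::plot(loo$beta, y, pch = 19, yaxt = "n",
                 xlim = range(loo$ci_low, loo$ci_high),
                 xlab = "IVW estimate without this SNP", ylab = "")
  graphics::segments(loo$ci_low, y, loo$ci_high, y)
  graphics::axis(2, at = y, labels = loo$snp_removed, las = 1,
                 cex.axis = 0.6)
  full <- attr(loo, "full")
  if (!is.null(full)) graphics::abline(v = full@beta, lty = 2)
  graphics::abline(v = 0, lty = 3, col = "grey50")
  invisible(path)
}
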