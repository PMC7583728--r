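# Static plot exports (the headless stand-in for interactive inspection).

#' Plot a trace with detected transitions
#'
#' Raw (or corrected) trace with event markers: openings in red, closings
#' in green, the idealized reconstruction overlaid.
#'
#' @param result an [AnalysisResult-class].
#' @param which `"corrected"` (default) or `"raw"`.
#' @param downsample plot every k-th sample (default keeps ~20k points).
#' @return Invisibly, NULL; draws on the active device.
#' @export
plotResult <- function(result, which = c("corrected", "raw"),
                       downsample = NULL) {
  which <- match.arg(which)
  tr <- if (which == "corrected") result@corrected else result@raw
  n <- length(tr@current)
  k <- if (is.null(downsample)) max(1L, floor(n / 20000)) else downsample
  idx <- seq(1L, n, by = k)
  tt <- traceTimes(tr)[idx]
  graphics::plot(tt, tr@current[idx], type = "l", col = "grey40",
                 xlab = "time [s]", ylab = "current [pA]",
                 main = sprintf("%s (%s)", result@traceId, which))
  if (nrow(result@events)) {
    ideal <- buildIdealized(tr, result@events)
    graphics::lines(tt, ideal@current[idx], col = "orange", lwd = 1.5)
    op <- result@events$direction == "opening"
    graphics::abline(v = result@events$t_trans_s[op], col = "red", lty = 3)
    graphics::abline(v = result@events$t_trans_s[!op], col = "darkgreen",
                     lty = 3)
  }
  invisible(NULL)
}

#' Plot a conductance histogram with fitted Gaussian components
#'
#' @param conductances event conductances (pS).
#' @param components fit from [fitConductanceHistogram()].
#' @param binWidth bin width (pS).
#' @return Invisibly, NULL.
#' @export
plotConductanceHist <- function(conductances, components = NULL,
                                binWidth = 10) {
  h <- .histCounts(conductances, binWidth)
  y <- h$counts / max(h$counts)
  graphics::plot(h$mids, y, type = "h", lwd = 4, col = "grey70",
                 xlab = "conductance [pS]", ylab = "normalized count")
  if (!is.null(components)) {
    xx <- seq(min(h$mids), max(h$mids), length.out = 400)
    tot <- rep(0, length(xx))
    for (k in seq_len(nrow(components))) {
      yy <- components$amplitude[k] *
        exp(-(xx - components$mean[k])^2 / (2 * components$sd[k]^2))
      graphics::lines(xx, yy, col = k + 1, lwd = 2)
      tot <- tot + yy
    }
    if (nrow(components) > 1) graphics::lines(xx, tot, col = 1, lty = 2)
  }
  invisible(NULL)
}
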