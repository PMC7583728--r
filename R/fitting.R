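# Error-function step fitting: exact amplitudes and transition kinetics.

# Build the fit window around t_trans, shrinking towards the midpoint of
# any neighbouring event that falls inside (so a second jump cannot
# contaminate the fit).
.fitWindow <- function(trace, tTrans, halfwindow, neighbors) {
  loT <- tTrans - halfwindow
  hiT <- tTrans + halfwindow
  for (nb in neighbors) {
    if (nb <= loT || nb >= hiT || nb == tTrans) next
    mid <- (nb + tTrans) / 2
    if (nb < tTrans) loT <- max(loT, mid) else hiT <- min(hiT, mid)
  }
  lo <- max(1L, timeToIndex(trace, loT))
  hi <- min(length(trace@current), timeToIndex(trace, hiT))
  c(lo, hi)
}

#' Fit one transition to the error-function step model
#'
#' Fits `f(t) = A * erf((t - t0)/B) + C` by Levenberg-Marquardt nonlinear
#' least squares to the trace samples in
#' `[t_trans - halfwindow, t_trans + halfwindow]` (window size 0.3 s = the
#' maximum transition time).  The transition amplitude is `a_trans = 2A`
#' and the characteristic transition time constant `tc_trans = B`.  If a
#' neighbouring event time falls inside the window, the window is shrunk to
#' the midpoint towards that neighbour before fitting; a neighbour closer
#' than 20 samples triggers a joint two-edge fit instead.
#'
#' By default the edge center `t0` is also fitted (initialized at
#' `t_trans`, bounded inside the window) because refined times are
#' quantized to the sampling grid; `fitCenter = FALSE` fixes `t0 = t_trans`.
#'
#' @param trace the [ChannelTrace-class] to fit on (baseline-corrected once
#'   a baseline is available).
#' @param tTrans refined transition time (s).
#' @param halfwindow fit half-window (s), default 0.15.
#' @param neighbors times (s) of other events on the trace.
#' @param fitCenter fit `t0` as a free parameter (default TRUE).
#' @param levelDiff optional TV level difference (pA) used as the amplitude
#'   initial guess and as the fallback amplitude on non-convergence.
#' @return An object of class `ErfFit`: list with `A` (pA), `B` (s),
#'   `C` (pA), `t_center` (s), `window` (c(start, end) s), `residual_rms`
#'   (pA), `converged`, `joint`, and the derived `a_trans` (= 2A, pA) and
#'   `tc_trans` (= B, s).  On non-convergence `converged = FALSE`,
#'   `a_trans` falls back to the local level difference and `tc_trans` is
#'   NA.
#' @examples
#' cfg <- simConfig(duration = 2, noiseSD = 0, transitionRate = 0)
#' ev <- data.frame(time_s = 1, amplitude_pA = 20, tc_ms = 5)
#' tr <- synthesizeTrace(cfg, ev)
#' fit <- fitTransition(tr, 1)
#' c(fit$a_trans, fit$tc_trans * 1000)
#' @export
fitTransition <- function(trace, tTrans, halfwindow = 0.15,
                          neighbors = numeric(0), fitCenter = TRUE,
                          levelDiff = NULL) {
  stopifnot(is(trace, "ChannelTrace"))
  fs <- trace@samplingRate
  near <- neighbors[abs(neighbors - tTrans) < 20 / fs &
                      abs(neighbors - tTrans) > 0]
  if (length(near))
    return(.fitTwoEdges(trace, tTrans, near[which.min(abs(near - tTrans))],
                        halfwindow, fitCenter, levelDiff))
  w <- .fitWindow(trace, tTrans, halfwindow, neighbors)
  if (w[2] - w[1] + 1L < 10L)
    stop("fit window contains fewer than 10 samples after readjustment")
  idx <- w[1]:w[2]
  tt <- trace@t0 + (idx - 1) / fs
  yy <- trace@current[idx]
  pre <- yy[tt < tTrans]; post <- yy[tt >= tTrans]
  if (!length(pre)) pre <- yy[1L]
  if (!length(post)) post <- yy[length(yy)]
  C0 <- mean(pre)
  A0 <- if (!is.null(levelDiff)) levelDiff / 2 else (mean(post) - mean(pre)) / 2
  bMax <- 2 * halfwindow            # maximum transition time (0.3 s default)
  bMin <- 0.02 / fs
  fits <- list()
  for (B0 in c(0.001, 0.0001, 0.01, 0.05)) {
    fit <- tryCatch({
      if (fitCenter) {
        minpack.lm::nlsLM(
          yy ~ A * erf((tt - t0) / B) + C,
          start = list(A = A0, B = B0, C = C0, t0 = tTrans),
          lower = c(-Inf, bMin, -Inf, tTrans - halfwindow / 2),
          upper = c(Inf, bMax, Inf, tTrans + halfwindow / 2),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          yy ~ A * erf((tt - tTrans) / B) + C,
          start = list(A = A0, B = B0, C = C0),
          lower = c(-Inf, bMin, -Inf), upper = c(Inf, bMax, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
    # accept immediately unless the fit ran into the B bound
    if (!is.null(fit) && coef(fit)[["B"]] < 0.95 * bMax) break
  }
  if (!length(fits)) {
    ld <- if (!is.null(levelDiff)) levelDiff else mean(post) - mean(pre)
    return(structure(list(
      A = ld / 2, B = NA_real_, C = C0, t_center = tTrans,
      window = tt[c(1L, length(tt))], residual_rms = NA_real_,
      converged = FALSE, joint = FALSE, a_trans = ld, tc_trans = NA_real_),
      class = "ErfFit"))
  }
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  cf <- coef(fit)
  structure(list(
    A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
    t_center = if (fitCenter) cf[["t0"]] else tTrans,
    window = tt[c(1L, length(tt))],
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    converged = TRUE, joint = FALSE,
    a_trans = 2 * cf[["A"]], tc_trans = abs(cf[["B"]])), class = "ErfFit")
}

# Joint fit of two erf edges closer than 20 samples; prevents amplitude
# cross-contamination that window shrinking alone cannot avoid.
.fitTwoEdges <- function(trace, tTrans, tOther, halfwindow, fitCenter,
                         levelDiff) {
  fs <- trace@samplingRate
  lo <- max(1L, timeToIndex(trace, min(tTrans, tOther) - halfwindow))
  hi <- min(length(trace@current),
            timeToIndex(trace, max(tTrans, tOther) + halfwindow))
  idx <- lo:hi
  tt <- trace@t0 + (idx - 1) / fs
  yy <- trace@current[idx]
  C0 <- mean(yy[tt < min(tTrans, tOther)])
  if (!is.finite(C0)) C0 <- yy[1L]
  A0 <- if (!is.null(levelDiff)) levelDiff / 2 else (yy[length(yy)] - yy[1L]) / 4
  bMax <- 2 * halfwindow; bMin <- 0.02 / fs
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A1 * erf((tt - t1) / B1) + A2 * erf((tt - t2) / B2) + C,
      start = list(A1 = A0, B1 = 0.001, A2 = A0, B2 = 0.001, C = C0,
                   t1 = tTrans, t2 = tOther),
      lower = c(-Inf, bMin, -Inf, bMin, -Inf, tTrans - 10 / fs,
                tOther - 10 / fs),
      upper = c(Inf, bMax, Inf, bMax, Inf, tTrans + 10 / fs,
                tOther + 10 / fs),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ld <- if (!is.null(levelDiff)) levelDiff else NA_real_
    return(structure(list(
      A = ld / 2, B = NA_real_, C = C0, t_center = tTrans,
      window = tt[c(1L, length(tt))], residual_rms = NA_real_,
      converged = FALSE, joint = TRUE, a_trans = ld, tc_trans = NA_real_),
      class = "ErfFit"))
  }
  cf <- coef(fit)
  structure(list(
    A = cf[["A1"]], B = cf[["B1"]], C = cf[["C"]],
    t_center = cf[["t1"]], window = tt[c(1L, length(tt))],
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    converged = TRUE, joint = TRUE,
    a_trans = 2 * cf[["A1"]], tc_trans = abs(cf[["B1"]])), class = "ErfFit")
}

#' @export
print.ErfFit <- function(x, ...) {
  cat(sprintf(
    "ErfFit: a_trans = %.4g pA, tc_trans = %.4g ms, C = %.4g pA%s%s\n",
    x$a_trans, 1000 * x$tc_trans, x$C,
    if (x$joint) " [joint]" else "",
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Classify transitions into conductance states
#'
#' An event belongs to the component whose one-SD interval
#' `[mean - sd, mean + sd]` contains its conductance; events outside every
#' interval are `"unclassified"`; events inside several intervals go to the
#' nearest mean in SD units.
#'
#' @param conductance numeric vector of event conductances (pS).
#' @param components data.frame with `label`, `mean`, `sd` (pS); see
#'   [defaultComponents()].
#' @return Character vector of component labels or `"unclassified"`.
#' @examples
#' classifyState(c(217, 79, 140), defaultComponents())
#' @export
classifyState <- function(conductance, components = defaultComponents()) {
  if (!nrow(components)) stop("components must be non-empty")
  z <- vapply(seq_len(nrow(components)), function(k)
    abs(conductance - components$mean[k]) / components$sd[k],
    numeric(length(conductance)))
  z <- matrix(z, nrow = length(conductance))
  inside <- z <= 1
  lab <- rep("unclassified", length(conductance))
  hit <- which(rowSums(inside) > 0)
  if (length(hit)) {
    zin <- z[hit, , drop = FALSE]
    zin[!inside[hit, , drop = FALSE]] <- Inf
    lab[hit] <- components$label[max.col(-zin, ties.method = "first")]
  }
  lab
}
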