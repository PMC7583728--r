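#' Default conductance components of the gating states
#'
#' The two-state template used for classification and as generative
#' defaults: a main open state of 217 +/- 66 pS and a subconductance
#' (residual) state of 80 +/- 28 pS (mean +/- SD).
#'
#' @return data.frame with columns `label`, `mean`, `sd` (pS).
#' @export
defaultComponents <- function() {
  data.frame(label = c("substate", "main"), mean = c(80, 217),
             sd = c(28, 66), stringsAsFactors = FALSE)
}

#' Construct analysis parameters
#'
#' All tunables of the idealization pipeline with their defaults.  See
#' [AnalysisParams-class] for the meaning of each setting.
#'
#' @param tMF running-median window (s).
#' @param tvdLambda TV regularization weight (pA scale).
#' @param tvdIterations TVD clipping iterations.
#' @param thresholdPS detection threshold (pS).
#' @param detectSmooth pre-difference boxcar half-width (s); NA: `tMF/6`.
#' @param refineStencil refinement derivative stencil half-width (s), default 10 ms.
#' @param refineHalfwindow TVD refinement half-window (s).
#' @param minSeparation candidate merge distance (s).
#' @param mergeGap maximum run gap treated as one split edge (s).
#' @param fitHalfwindow erf-fit half-window (s).
#' @param fitCenter fit the edge center time as a free parameter.
#' @param maxCycles maximum baseline reanalysis cycles.
#' @param components state-classification components (label/mean/sd in pS).
#' @param openLevelPS open level for NPo (NA: largest component mean).
#' @param thresholdFraction open-closed discriminator fraction.
#' @param edgeGuard end-of-trace guard (s; NA: `tMF/2`).
#' @param baselineFamilies baseline families to try, or a single family name
#'   to force.
#' @return An [AnalysisParams-class] object.
#' @examples
#' analysisParams(thresholdPS = 80)
#' @export
analysisParams <- function(tMF = 0.3, tvdLambda = 10000, tvdIterations = 30,
                           thresholdPS = 60, detectSmooth = NA_real_,
                           refineStencil = 0.010, refineHalfwindow = 0.3,
                           minSeparation = 0.15, mergeGap = 0.01,
                           fitHalfwindow = 0.15, fitCenter = TRUE,
                           maxCycles = 5, components = defaultComponents(),
                           openLevelPS = NA_real_, thresholdFraction = 0.5,
                           edgeGuard = NA_real_,
                           baselineFamilies = c("single_exp", "double_exp",
                                                "log", "linear")) {
  new("AnalysisParams", tMF = tMF, tvdLambda = tvdLambda,
      tvdIterations = as.integer(tvdIterations), thresholdPS = thresholdPS,
      detectSmooth = detectSmooth, refineStencil = refineStencil,
      refineHalfwindow = refineHalfwindow, minSeparation = minSeparation,
      mergeGap = mergeGap, fitHalfwindow = fitHalfwindow,
      fitCenter = isTRUE(fitCenter), maxCycles = as.integer(maxCycles),
      components = components, openLevelPS = openLevelPS,
      thresholdFraction = thresholdFraction, edgeGuard = edgeGuard,
      baselineFamilies = baselineFamilies)
}

.defaultBaselineParams <- function(family) {
  switch(family,
    none = numeric(0),
    linear = c(a = 1.5, b = 0),
    single_exp = c(a = 45, b = 5, c = 0),
    double_exp = c(a = 30, b = 3, c = 20, d = 12, e = 0),
    log = c(a = 8, b = 0, c = 0.25),
    stop("unknown baseline family '", family, "'")
  )
}

#' Construct a simulation configuration
#'
#' Defaults emulate a control-condition whole-cell recording: 30 s at
#' 4 kHz stepped to +70 mV, one channel, 30 pS-equivalent Gaussian noise,
#' per-event conductances from the main (217 +/- 66 pS) or substate
#' (80 +/- 28 pS) Gaussian with a 5.3% substate share, 14.5 transitions per
#' 30 s, transition time constants exponential with mean 5.2 ms truncated
#' at 300 ms, and no baseline drift.  See [SimConfig-class].
#'
#' @param duration,samplingRate,vm,noiseSD,nChannels,stateLevels see
#'   [SimConfig-class].
#' @param transitionRate,tcTau,tcMax,substateFraction,dwellMean,minSojourn,margin
#'   see [SimConfig-class].
#' @param baselineFamily,baselineParams,seed see [SimConfig-class];
#'   `baselineParams = NULL` takes family defaults sized at about three
#'   main-state amplitudes of drift per trace.
#' @return A validated [SimConfig-class] object.  Invalid fields raise an
#'   error naming the field.
#' @examples
#' cfg <- simConfig(seed = 1)
#' sim <- simulateTrace(cfg)
#' sim$trace
#' @export
simConfig <- function(duration = 30, samplingRate = 4000, vm = 70,
                      noiseSD = 30, nChannels = 1,
                      stateLevels = defaultComponents(),
                      transitionRate = 14.5 / 30, tcTau = 5.2, tcMax = 300,
                      substateFraction = 0.053, dwellMean = 1,
                      minSojourn = 0.4, margin = 0.5,
                      baselineFamily = "none", baselineParams = NULL,
                      seed = NA) {
  if (is.null(baselineParams))
    baselineParams <- .defaultBaselineParams(
      match.arg(baselineFamily,
                c("none", "linear", "single_exp", "double_exp", "log")))
  new("SimConfig", duration = as.numeric(duration),
      samplingRate = as.numeric(samplingRate), vm = as.numeric(vm),
      noiseSD = as.numeric(noiseSD), nChannels = as.integer(nChannels),
      stateLevels = stateLevels, transitionRate = as.numeric(transitionRate),
      tcTau = as.numeric(tcTau), tcMax = as.numeric(tcMax),
      substateFraction = as.numeric(substateFraction),
      dwellMean = as.numeric(dwellMean),
      minSojourn = as.numeric(minSojourn), margin = as.numeric(margin),
      baselineFamily = baselineFamily,
      baselineParams = {
        bp <- unlist(baselineParams)
        if (length(bp)) storage.mode(bp) <- "double"
        else bp <- numeric(0)
        bp
      },
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}
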