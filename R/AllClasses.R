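#' ChannelTrace: a uniformly sampled current record
#'
#' The universal input of the pipeline: a vector of membrane currents (pA)
#' sampled at a fixed rate, together with the step potential at which the
#' trace was recorded.  The time of sample `i` (1-based) is
#' `t0 + (i - 1) / samplingRate`.
#'
#' @slot current numeric, membrane current in pA.
#' @slot samplingRate numeric, samples per second (Hz).
#' @slot vm numeric, step potential in mV (sign carried; openings are
#'   positive-going at positive `vm`).
#' @slot t0 numeric, time of the first sample in seconds.
#' @slot metadata list, free-form condition labels.
#'
#' @seealso [channelTrace()], [analyzeTrace()]
#' @exportClass ChannelTrace
setClass("ChannelTrace",
  representation(
    current = "numeric",
    samplingRate = "numeric",
    vm = "numeric",
    t0 = "numeric",
    metadata = "list"
  ),
  prototype(current = numeric(0), samplingRate = 4000, vm = 70, t0 = 0,
            metadata = list())
)

setValidity("ChannelTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@vm) != 1L || !is.finite(object@vm))
    msg <- c(msg, "vm must be a single finite number (mV)")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number (s)")
  if (anyNA(object@current) || any(!is.finite(object@current)))
    msg <- c(msg, "current must contain only finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelTrace
#'
#' @param current numeric vector of currents (pA).
#' @param samplingRate sampling rate in Hz.
#' @param vm step potential in mV; must be non-zero for conductance
#'   thresholding downstream.
#' @param t0 start time in seconds.
#' @param metadata named list of condition labels.
#' @return A [ChannelTrace-class] object.
#' @examples
#' tr <- channelTrace(rnorm(4000, sd = 2.1), samplingRate = 4000, vm = 70)
#' tr
#' @export
channelTrace <- function(current, samplingRate = 4000, vm = 70, t0 = 0,
                         metadata = list()) {
  new("ChannelTrace", current = as.numeric(current),
      samplingRate = as.numeric(samplingRate), vm = as.numeric(vm),
      t0 = as.numeric(t0), metadata = metadata)
}

#' SimConfig: generative settings for synthetic gating traces
#'
#' Describes the statistical structure the analysis assumes: three-state
#' gating (closed / substate / main open state) with per-event conductances
#' drawn from state Gaussians, erf-shaped transition edges with
#' exponentially distributed time constants, i.i.d. Gaussian background
#' noise specified in conductance units, stackable independent channels and
#' optional baseline drift from one of four families.  Defaults reproduce a
#' control-condition recording: 30 s at 4 kHz, +70 mV, 30 pS noise, states
#' 217 +/- 66 pS (main) and 80 +/- 28 pS (substate), 14.5 transitions per
#' 30 s with a 5.3% substate share.
#'
#' @slot duration seconds of recording.
#' @slot samplingRate Hz.
#' @slot vm step potential, mV.
#' @slot noiseSD background noise SD in pS-equivalent (converted to pA as
#'   `noiseSD * |vm| / 1000`).
#' @slot nChannels number of independent stackable channels.
#' @slot stateLevels data.frame with columns `label`, `mean` (pS), `sd` (pS)
#'   for the substate and main state.
#' @slot transitionRate expected transitions (openings + closings) per
#'   second per channel.
#' @slot tcTau mean (ms) of the exponential distribution of transition time
#'   constants.
#' @slot tcMax truncation (ms) of the transition time constant; 300 ms is
#'   the slowest transition the analysis window accommodates.
#' @slot substateFraction probability that a gating event targets the
#'   substate rather than the main state.
#' @slot dwellMean mean (s) of the open dwell before the paired closing.
#' @slot minSojourn floor (s) on open dwells and closed gaps; sojourns are
#'   drawn as `minSojourn + Exp(mean - minSojourn)` so means are
#'   preserved.  The default 0.4 s keeps simulated gating within the
#'   resolvable regime of a 0.3 s median filter (which removes pulses
#'   shorter than half its window); set 0 to emulate flicker gating.
#' @slot margin events are confined to `(margin, duration - margin)` s.
#' @slot baselineFamily one of `"none"`, `"linear"`, `"single_exp"`,
#'   `"double_exp"`, `"log"`.
#' @slot baselineParams named numeric of family coefficients (see
#'   [fitBaseline()] for the parameterizations); defaults give a drift of
#'   roughly three main-state amplitudes over the trace.
#' @slot seed integer seed (NA to leave the RNG state untouched).
#'
#' @seealso [simConfig()], [simulateTrace()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    duration = "numeric", samplingRate = "numeric", vm = "numeric",
    noiseSD = "numeric", nChannels = "integer", stateLevels = "data.frame",
    transitionRate = "numeric", tcTau = "numeric", tcMax = "numeric",
    substateFraction = "numeric", dwellMean = "numeric",
    minSojourn = "numeric", margin = "numeric",
    baselineFamily = "character", baselineParams = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm, pos = TRUE) {
    if (length(x) != 1L || !is.finite(x) || (pos && x <= 0))
      sprintf("field '%s' must be a single %s number", nm,
              if (pos) "positive" else "finite") else character(0)
  }
  msg <- c(msg, chk1(object@duration, "duration"),
           chk1(object@samplingRate, "samplingRate"),
           chk1(object@vm, "vm", pos = FALSE),
           chk1(object@tcTau, "tcTau"), chk1(object@tcMax, "tcMax"),
           chk1(object@dwellMean, "dwellMean"))
  if (!is.finite(object@minSojourn) || object@minSojourn < 0 ||
      object@minSojourn >= object@dwellMean)
    msg <- c(msg, "field 'minSojourn' must satisfy 0 <= minSojourn < dwellMean")
  if (object@vm == 0) msg <- c(msg, "field 'vm' must be non-zero")
  if (!is.finite(object@noiseSD) || object@noiseSD < 0)
    msg <- c(msg, "field 'noiseSD' must be >= 0")
  if (!is.finite(object@transitionRate) || object@transitionRate < 0)
    msg <- c(msg, "field 'transitionRate' must be >= 0")
  if (object@nChannels < 1L)
    msg <- c(msg, "field 'nChannels' must be >= 1")
  if (!is.finite(object@substateFraction) || object@substateFraction < 0 ||
      object@substateFraction > 1)
    msg <- c(msg, "field 'substateFraction' must lie in [0, 1]")
  sl <- object@stateLevels
  if (!all(c("label", "mean", "sd") %in% names(sl)) || nrow(sl) < 1L)
    msg <- c(msg, "field 'stateLevels' needs columns label, mean, sd")
  else {
    if (any(sl$mean <= 0)) msg <- c(msg, "field 'stateLevels': all conductances must be > 0")
    if (any(sl$sd < 0)) msg <- c(msg, "field 'stateLevels': SDs must be >= 0")
  }
  if (!is.finite(object@margin) || object@margin < 0 ||
      2 * object@margin >= object@duration)
    msg <- c(msg, "field 'margin' must satisfy 0 <= 2*margin < duration")
  if (!object@baselineFamily %in%
      c("none", "linear", "single_exp", "double_exp", "log"))
    msg <- c(msg, "field 'baselineFamily' must be one of none/linear/single_exp/double_exp/log")
  if (length(msg)) msg else TRUE
})

#' BaselineModel: a fitted slow-drift function
#'
#' One of four drift families fitted by nonlinear least squares to the
#' event-free residual trace:
#' \describe{
#'   \item{single_exp}{`a * (1 - exp(-x/b)) + c`}
#'   \item{double_exp}{`a * (1 - exp(-x/b)) + c * (1 - exp(-x/d)) + e`}
#'   \item{log}{`a * log(x + c) + b`}
#'   \item{linear}{`a * x + b`}
#' }
#' plus a `"constant"` fallback.  `allFits` retains every attempted family
#' (params, rss, aic, converged) for inspection.
#'
#' @slot family character, the selected family.
#' @slot params named numeric coefficients.
#' @slot rss residual sum of squares (pA^2).
#' @slot aic model-selection score of the winning family.
#' @slot allFits list of per-family fit records.
#' @slot note character; non-empty when a fallback or override applied.
#' @seealso [fitBaseline()], [baselineValues()]
#' @exportClass BaselineModel
setClass("BaselineModel",
  representation(family = "character", params = "numeric", rss = "numeric",
                 aic = "numeric", allFits = "list", note = "character"),
  prototype(family = "constant", params = c(a = 0), rss = NA_real_,
            aic = NA_real_, allFits = list(), note = "")
)

#' AnalysisParams: tunable settings of the idealization pipeline
#'
#' @slot tMF running-median window, seconds (default 0.3).
#' @slot tvdLambda TV regularization weight, applied to currents in pA at
#'   native sampling (default 10000; scale-dependent).
#' @slot tvdIterations clipping iterations of the TVD solver (default 30).
#' @slot thresholdPS detection threshold in pS (default 60, i.e. twice the
#'   30 pS background noise SD).
#' @slot detectSmooth boxcar half-width (s) applied to the median-filtered
#'   trace before differencing, so that order-statistic jitter of the
#'   running median does not shatter the monotone runs (NA: `tMF/6`).
#' @slot refineStencil half-width (s) of the symmetric-difference stencil
#'   used as the derivative estimate during refinement (default 2.5 ms).
#' @slot refineHalfwindow half-window (s) around the approximate time in
#'   which the TVD derivative is searched (default 0.3).
#' @slot minSeparation same-direction candidates closer than this (s) are
#'   candidates for merging (default 0.15).
#' @slot mergeGap maximum gap (s) between two same-sign derivative runs for
#'   them to count as fragments of one edge (default 0.01).
#' @slot fitHalfwindow half-window (s) of the erf fit (default 0.15; window
#'   size equals the 0.3 s maximum transition time).
#' @slot fitCenter logical; also fit the edge center time (default TRUE).
#' @slot maxCycles maximum baseline-reanalysis cycles (default 5).
#' @slot components data.frame (`label`, `mean`, `sd`, pS) used for state
#'   classification and the default open level.
#' @slot openLevelPS conductance of the fully open level for NPo (NA: use
#'   the largest component mean).
#' @slot thresholdFraction open-closed discriminator as a fraction of the
#'   open level (default 0.5: half-way).
#' @slot edgeGuard candidates within this margin (s) of the trace ends are
#'   ignored (NA: `tMF/2`).
#' @slot baselineFamilies families tried by [fitBaseline()]; the lowest-AIC
#'   one wins unless a single family is named.
#' @seealso [analysisParams()], [analyzeTrace()]
#' @exportClass AnalysisParams
setClass("AnalysisParams",
  representation(
    tMF = "numeric", tvdLambda = "numeric", tvdIterations = "integer",
    thresholdPS = "numeric", detectSmooth = "numeric",
    refineStencil = "numeric", refineHalfwindow = "numeric",
    minSeparation = "numeric", mergeGap = "numeric",
    fitHalfwindow = "numeric", fitCenter = "logical", maxCycles = "integer",
    components = "data.frame", openLevelPS = "numeric",
    thresholdFraction = "numeric", edgeGuard = "numeric",
    baselineFamilies = "character"
  )
)

setValidity("AnalysisParams", function(object) {
  msg <- character(0)
  pos <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      sprintf("'%s' must be a single positive number", nm) else character(0)
  }
  msg <- c(msg, pos(object@tMF, "tMF"), pos(object@thresholdPS, "thresholdPS"),
           pos(object@refineHalfwindow, "refineHalfwindow"),
           pos(object@fitHalfwindow, "fitHalfwindow"))
  if (object@tvdLambda < 0) msg <- c(msg, "'tvdLambda' must be >= 0")
  if (object@tvdIterations < 1L) msg <- c(msg, "'tvdIterations' must be >= 1")
  if (object@minSeparation < 0) msg <- c(msg, "'minSeparation' must be >= 0")
  if (object@mergeGap < 0) msg <- c(msg, "'mergeGap' must be >= 0")
  if (object@maxCycles < 1L) msg <- c(msg, "'maxCycles' must be >= 1")
  if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
    msg <- c(msg, "'thresholdFraction' must lie in (0, 1]")
  if (!all(c("label", "mean", "sd") %in% names(object@components)))
    msg <- c(msg, "'components' needs columns label, mean, sd")
  if (length(msg)) msg else TRUE
})

#' AnalysisResult: the full per-trace analysis record
#'
#' Aggregates everything [analyzeTrace()] produces: the corrected trace, the
#' event table, the fitted baseline, the gating summary and an audit log of
#' manual edits and reanalysis iterations.  [addEvent()] and [removeEvent()]
#' operate on this object and keep all downstream fields consistent.
#'
#' @slot traceId character identifier.
#' @slot raw,corrected,tvd [ChannelTrace-class]: the input, the
#'   baseline-corrected trace and the TV-denoised corrected trace.
#' @slot events data.frame, one row per transition (see [fitTransition()]
#'   for the columns).
#' @slot baseline [BaselineModel-class].
#' @slot summary one-row data.frame of gating metrics (see [computeNPo()]).
#' @slot auditLog list of manual-edit and iteration records.
#' @slot iterations reanalysis cycles run.
#' @slot converged logical; FALSE when the event set was still changing at
#'   `maxCycles`.
#' @slot params the [AnalysisParams-class] used.
#' @exportClass AnalysisResult
setClass("AnalysisResult",
  representation(
    traceId = "character", raw = "ChannelTrace", corrected = "ChannelTrace",
    tvd = "ChannelTrace", events = "data.frame", baseline = "BaselineModel",
    summary = "data.frame", auditLog = "list", iterations = "integer",
    converged = "logical", params = "AnalysisParams"
  )
)
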