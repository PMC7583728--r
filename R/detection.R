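# Candidate detection on the median-filtered trace and transition-time
# refinement on the TV-denoised trace.

# Sign of the current step for a given event direction: openings move the
# current away from baseline, i.e. positive-going at positive vm.
stepSign <- function(direction, vm) {
  ifelse(direction == "opening", 1, -1) * sign(vm)
}

#' Detect candidate transitions on a median-filtered trace
#'
#' Transitions are located where the derivative of the median-filtered
#' signal exceeds a conductance threshold.  Because a 0.3 s median window
#' spreads an edge into a ramp, per-sample first differences of the same
#' sign are accumulated into monotone runs and each run whose cumulative
#' amplitude exceeds `thresholdPS * |vm| / 1000` pA yields one candidate,
#' placed at the steepest difference of the run.  Same-sign runs separated
#' by less than `mergeGap` seconds (fragments of one noise-split edge) are
#' coalesced before thresholding when their steepest points fall within
#' `minSeparation` of each other; plateau-separated events are never
#' merged.  Candidates within `edgeGuard` of the trace ends, where the
#' shrinking median windows are unreliable, are discarded.
#'
#' Sub-threshold events are invisible at this stage by design (the
#' threshold serves the baseline-isolation pass); they can still be added
#' with [addEvent()].
#'
#' @param medianTrace a median-filtered [ChannelTrace-class] (see
#'   [medianFilter()]); `vm` must be non-zero.
#' @param params an [AnalysisParams-class].
#' @return data.frame with one row per candidate: `time_s` (steepest
#'   point), `direction` ("opening"/"closing"), `approx_amplitude_pA`
#'   (signed cumulative run amplitude), `run_start_s`, `run_end_s`.
#' @examples
#' tr <- channelTrace(c(rep(0, 2000), rep(15.19, 2000)))
#' detectCandidates(medianFilter(tr, 0.1), analysisParams())
#' @export
detectCandidates <- function(medianTrace, params = analysisParams()) {
  stopifnot(is(medianTrace, "ChannelTrace"))
  if (medianTrace@vm == 0)
    stop("vm = 0: conductance threshold undefined (configuration error)")
  x <- medianTrace@current
  fs <- medianTrace@samplingRate
  empty <- data.frame(time_s = numeric(0), direction = character(0),
                      approx_amplitude_pA = numeric(0),
                      run_start_s = numeric(0), run_end_s = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(x) < 2L) return(empty)
  thrPa <- psToPa(params@thresholdPS, abs(medianTrace@vm))
  # light boxcar so order-statistic jitter of the running median does not
  # shatter the monotone runs of an edge ramp
  smoothS <- if (is.na(params@detectSmooth)) params@tMF / 6
    else params@detectSmooth
  x <- boxcarMean(x, round(smoothS * fs))
  d <- diff(x)
  s <- sign(d)
  rl <- rle(s)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values != 0
  if (!any(keep)) return(empty)
  runs <- data.frame(a = starts[keep], b = ends[keep], sgn = rl$values[keep])

  # coalesce fragments of one split edge
  gapMax <- params@mergeGap * fs
  merged <- list()
  cur <- runs[1L, ]
  steepest <- function(a, b) a - 1L + which.max(abs(d[a:b]))
  if (nrow(runs) >= 2L) {
    for (k in 2:nrow(runs)) {
      nxt <- runs[k, ]
      tcur <- steepest(cur$a, cur$b); tnxt <- steepest(nxt$a, nxt$b)
      if (nxt$sgn == cur$sgn && (nxt$a - cur$b) <= gapMax &&
          (tnxt - tcur) / fs <= params@minSeparation) {
        cur$b <- nxt$b
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  runs <- do.call(rbind, merged)

  amp <- x[runs$b + 1L] - x[runs$a]
  sel <- abs(amp) >= thrPa
  if (!any(sel)) return(empty)
  runs <- runs[sel, , drop = FALSE]; amp <- amp[sel]
  steep <- mapply(steepest, runs$a, runs$b)
  t_steep <- diffTime(medianTrace, steep)
  guard <- if (is.na(params@edgeGuard)) params@tMF / 2 else params@edgeGuard
  tSpan <- c(medianTrace@t0, medianTrace@t0 + (length(x) - 1) / fs)
  inb <- t_steep > tSpan[1] + guard & t_steep < tSpan[2] - guard
  runs <- runs[inb, , drop = FALSE]; amp <- amp[inb]; t_steep <- t_steep[inb]
  if (!nrow(runs)) return(empty)
  dirn <- ifelse(amp * sign(medianTrace@vm) > 0, "opening", "closing")
  data.frame(time_s = t_steep, direction = dirn, approx_amplitude_pA = amp,
             run_start_s = diffTime(medianTrace, runs$a),
             run_end_s = diffTime(medianTrace, runs$b),
             stringsAsFactors = FALSE)
}

#' Refine a candidate time on the TV-denoised trace
#'
#' The median filter distorts event times, so each approximate candidate
#' time is refined to the position of the maximum-magnitude,
#' sign-consistent derivative of the TV-denoised signal within
#' `[time - halfwindow, time + halfwindow]`.  The derivative is estimated
#' with a symmetric-difference stencil of half-width `stencil` seconds,
#' which keeps slow (large time constant) edges detectable above the
#' derivative noise of the denoised trace while leaving the position of
#' the maximum at the edge center.
#'
#' @param tvdTrace a TV-denoised [ChannelTrace-class] (see [tvdDenoise()]).
#' @param time approximate candidate time (s).
#' @param direction `"opening"` or `"closing"`.
#' @param halfwindow search half-window in seconds (default 0.3).
#' @param stencil derivative stencil half-width in seconds (default 2.5 ms).
#' @return The refined time (s).  If no sign-consistent derivative exists
#'   in the window the candidate is unrefinable: the input time is returned
#'   with attribute `refined = FALSE` and a warning.
#' @export
refineEventTime <- function(tvdTrace, time, direction, halfwindow = 0.3,
                            stencil = 0.0025) {
  stopifnot(is(tvdTrace, "ChannelTrace"))
  x <- tvdTrace@current
  fs <- tvdTrace@samplingRate
  n <- length(x)
  lo <- max(1L, timeToIndex(tvdTrace, time - halfwindow))
  hi <- min(n, timeToIndex(tvdTrace, time + halfwindow))
  if (hi - lo < 1L) stop("refinement window does not intersect the trace")
  h <- max(1L, round(stencil * fs))
  d <- wideDiff(x, h)[lo:hi]
  sgn <- stepSign(direction, tvdTrace@vm)
  ds <- d * sgn
  if (all(ds <= 0)) {
    warning("no sign-consistent derivative in window; candidate kept at ",
            "approximate time ", signif(time, 6), " s")
    return(structure(time, refined = FALSE))
  }
  i <- which.max(ds)
  structure(tvdTrace@t0 + (lo - 1L + i - 1L) / fs, refined = TRUE)
}
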