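# Denoising primitives: windowed running median and 1-D total variation
# denoising (TVD).

#' Running-median filter
#'
#' Replaces every sample by the median of a centred window of `tMF` seconds.
#' Compared to low-pass filtering this removes high-frequency noise while
#' preserving step amplitudes and keeping slow baseline drift
#' distinguishable from true gating events.  Edge policy: windows shrink at
#' the trace ends; even-sized windows use the midpoint of the two central
#' order statistics.
#'
#' @param trace a [ChannelTrace-class].
#' @param tMF window length in seconds (default 0.3, chosen to exceed the
#'   slowest ~300 ms transitions).
#' @return A [ChannelTrace-class] of identical length and metadata.
#' @examples
#' tr <- channelTrace(c(rep(0, 50), rep(10, 50)), samplingRate = 100)
#' medianFilter(tr, tMF = 0.1)
#' @export
medianFilter <- function(trace, tMF = 0.3) {
  stopifnot(is(trace, "ChannelTrace"))
  if (!is.finite(tMF) || tMF <= 0) stop("tMF must be a positive time in seconds")
  w <- max(1L, round(tMF * trace@samplingRate))
  out <- trace
  out@current <- .run_median_cpp(trace@current, as.integer(w))
  out
}

#' Total variation denoising
#'
#' Minimizes `1/2 * sum((y - x)^2) + lambda * sum(|diff(x)|)` by
#' majorization-minimization iterative clipping on the dual.  TV denoising
#' removes noise without blurring the sharp transition edges that carry the
#' event timing.  `lambda = 0` returns the input unchanged; as `lambda`
#' grows the output's total variation shrinks towards a constant.  With the
#' default 30 iterations the solver is deliberately under-converged and
#' acts as an edge-preserving smoother whose strength is set by the
#' iteration count; pass a large `iterations` together with `tol > 0` to
#' converge to the exact TV proximal operator (cross-checked against
#' [tvTautString()] in the test suite).
#'
#' @param trace a [ChannelTrace-class].
#' @param lambda regularization weight, on the scale of the trace samples
#'   (pA) at native sampling; scale-dependent.
#' @param iterations clipping iterations (default 30).
#' @param tol early-stop tolerance on the maximum per-sample change; 0
#'   (default) runs exactly `iterations` iterations.
#' @return A [ChannelTrace-class] of identical length and metadata.
#' @export
tvdDenoise <- function(trace, lambda = 10000, iterations = 30, tol = 0) {
  stopifnot(is(trace, "ChannelTrace"))
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (iterations < 1) stop("iterations must be >= 1")
  out <- trace
  out@current <- .tvd_clip_cpp(trace@current, lambda, as.integer(iterations),
                               tol)
  out
}
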