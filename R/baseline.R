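# Baseline drift isolation: idealized-trace subtraction, four-family drift
# fitting, and the iterative reanalysis loop.

#' Build the idealized (event-only) trace
#'
#' Piecewise reconstruction of the channel levels: the cumulative sum of
#' the signed transition amplitudes, each rendered as an erf edge with the
#' event's fitted time constant (instantaneous where the time constant is
#' missing) so the residual near edges is unbiased.  Subtracting this from
#' the raw trace isolates baseline drift plus noise.
#'
#' @param trace the reference [ChannelTrace-class] (supplies grid and
#'   metadata).
#' @param events data.frame with at least `t_trans_s`, `a_trans_pA`
#'   (signed) and `tc_trans_ms`; `t_center_s` is used when present.
#' @return A [ChannelTrace-class] holding the idealized samples (zero where
#'   no channel is open).
#' @export
buildIdealized <- function(trace, events) {
  stopifnot(is(trace, "ChannelTrace"))
  out <- trace
  n <- length(trace@current)
  x <- numeric(n)
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$t_trans_s), , drop = FALSE]
    times <- traceTimes(trace)
    tc <- events$tc_trans_ms
    tc[is.na(tc)] <- 0
    tctr <- if ("t_center_s" %in% names(events)) events$t_center_s else
      events$t_trans_s
    tctr[is.na(tctr)] <- events$t_trans_s[is.na(tctr)]
    for (k in seq_len(nrow(events)))
      x <- addErfEdge(x, times, tctr[k], events$a_trans_pA[k], tc[k] / 1000)
    lev <- cumsum(events$a_trans_pA) * sign(trace@vm)
    tol <- 0.5 * min(abs(events$a_trans_pA))
    if (min(lev) < -tol)
      warning("idealized level drops below the closed state; ",
              "a closing transition may be spurious or an opening missed")
  }
  out@current <- x
  out@metadata$sourceEvents <- if (is.null(events)) 0L else nrow(events)
  out
}

.familyPar <- function(family) {
  switch(family, linear = c("a", "b"), single_exp = c("a", "b", "c"),
         double_exp = c("a", "b", "c", "d", "e"), log = c("a", "b", "c"),
         constant = "a")
}

# least-squares fit of one drift family on (x, y); returns list or NULL
.fitFamily <- function(family, x, y) {
  T <- max(x)
  rng <- y[length(y)] - y[1L]
  fit <- tryCatch(switch(family,
    linear = {
      m <- lm(y ~ x)
      list(params = c(a = unname(coef(m)[2]), b = unname(coef(m)[1])),
           rss = sum(stats::residuals(m)^2))
    },
    single_exp = {
      m <- minpack.lm::nlsLM(y ~ a * (1 - exp(-x / b)) + c,
        start = list(a = ifelse(rng == 0, 1, rng), b = T / 3, c = y[1L]),
        lower = c(-Inf, T * 1e-4, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = coef(m), rss = stats::deviance(m))
    },
    double_exp = {
      m <- minpack.lm::nlsLM(
        y ~ a * (1 - exp(-x / b)) + c * (1 - exp(-x / d)) + e,
        start = list(a = rng / 2, b = T / 3, c = rng / 2, d = T / 10,
                     e = y[1L]),
        lower = c(-Inf, T * 1e-4, -Inf, T * 1e-4, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300))
      list(params = coef(m), rss = stats::deviance(m))
    },
    log = {
      dx <- stats::median(diff(x))
      m <- minpack.lm::nlsLM(y ~ a * log(x + c) + b,
        start = list(a = ifelse(rng == 0, 1, rng / log(T / dx + 1)),
                     b = y[1L], c = dx),
        lower = c(-Inf, -Inf, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = coef(m), rss = stats::deviance(m))
    },
    stop("unknown family '", family, "'")), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  k <- length(fit$params) + 1   # + residual variance
  fit$aic <- length(y) * log(fit$rss / length(y)) + 2 * k
  fit$converged <- TRUE
  fit$params <- setNames(as.numeric(fit$params), .familyPar(family))
  fit
}

#' Fit the baseline drift of an event-free residual trace
#'
#' Fits the residual (raw minus idealized trace) to four drift families by
#' nonlinear least squares -- single exponential `a(1 - exp(-x/b)) + c`,
#' double exponential `a(1 - exp(-x/b)) + c(1 - exp(-x/d)) + e`,
#' logarithmic `a ln(x + c) + b` and linear `a x + b`, with `x` the time
#' since trace start -- and selects the family with the lowest AIC (all
#' fits are retained in `allFits`).  A family that fails to converge is
#' skipped; if all fail, a constant (mean) baseline is returned with a
#' warning.  Fitting uses at most `maxPoints` evenly spaced samples; drift
#' is slow by definition, so decimation does not affect the fit.
#'
#' @param residual a [ChannelTrace-class] of residual samples.
#' @param families drift families to try; name a single one to force it.
#' @param maxPoints decimation cap for the fit (default 20000).
#' @return A [BaselineModel-class].
#' @seealso [baselineValues()], [correctAndReanalyze()]
#' @export
fitBaseline <- function(residual,
                        families = c("single_exp", "double_exp", "log",
                                     "linear"),
                        maxPoints = 20000) {
  stopifnot(is(residual, "ChannelTrace"))
  y <- residual@current
  n <- length(y)
  families <- match.arg(families,
    c("single_exp", "double_exp", "log", "linear"), several.ok = TRUE)
  maxP <- max(vapply(families, function(f) length(.familyPar(f)), numeric(1)))
  if (n < 10 * maxP)
    stop("residual too short: need at least 10 samples per parameter")
  step <- max(1L, floor(n / maxPoints))
  idx <- seq(1L, n, by = step)
  x <- (idx - 1) / residual@samplingRate
  fits <- lapply(families, .fitFamily, x = x, y = y[idx])
  names(fits) <- families
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    warning("no baseline family converged; using constant (mean) baseline")
    mu <- mean(y)
    return(new("BaselineModel", family = "constant", params = c(a = mu),
               rss = sum((y - mu)^2), aic = NA_real_, allFits = list(),
               note = "all families failed; constant fallback"))
  }
  fits <- fits[ok]
  best <- names(fits)[which.min(vapply(fits, `[[`, numeric(1), "aic"))]
  new("BaselineModel", family = best, params = fits[[best]]$params,
      rss = fits[[best]]$rss, aic = fits[[best]]$aic, allFits = fits,
      note = if (all(ok)) "" else
        paste("families failed to converge:",
              paste(families[!ok], collapse = ", ")))
}

#' Evaluate a fitted baseline model
#'
#' @param model a [BaselineModel-class].
#' @param times numeric times in seconds since trace start.
#' @return Numeric drift values (pA) at `times`.
#' @export
baselineValues <- function(model, times) {
  stopifnot(is(model, "BaselineModel"))
  p <- as.list(model@params)
  .baselineFun(model@family, p, times)
}

# subtract a baseline model from a trace
.applyBaseline <- function(trace, model) {
  out <- trace
  out@current <- trace@current -
    baselineValues(model, traceTimes(trace) - trace@t0)
  out
}

#' Baseline-correct a trace and reanalyze until the event set is stable
#'
#' Implements the iterative drift-removal loop: subtract the idealized
#' trace built from the current events, fit the baseline to the remainder,
#' subtract the fitted drift from the raw trace, re-run the full detection
#' and fitting chain on the corrected trace, and repeat until the event set
#' no longer changes (or `params@maxCycles` cycles, in which case the last
#' iteration is returned flagged as non-converged).
#'
#' @param trace the raw [ChannelTrace-class].
#' @param params an [AnalysisParams-class].
#' @param firstPass optional event table from an initial detection pass on
#'   the raw trace (computed internally when NULL).
#' @return list with `corrected` ([ChannelTrace-class]), `events`
#'   (data.frame), `baseline` ([BaselineModel-class]), `iterations`,
#'   `converged`.
#' @seealso [analyzeTrace()], which wraps this loop and adds metrics.
#' @export
correctAndReanalyze <- function(trace, params = analysisParams(),
                                firstPass = NULL) {
  stopifnot(is(trace, "ChannelTrace"))
  events <- if (is.null(firstPass)) .detectAndFit(trace, params)$events
    else firstPass
  fs <- trace@samplingRate
  sig <- function(ev) paste(round(ev$t_trans_s * fs), ev$direction,
                            collapse = ";")
  corrected <- trace; bl <- new("BaselineModel")
  converged <- FALSE
  it <- 0L
  for (cycle in seq_len(params@maxCycles)) {
    it <- cycle
    ideal <- buildIdealized(trace, events)
    resid <- trace
    resid@current <- trace@current - ideal@current
    bl <- fitBaseline(resid, families = params@baselineFamilies)
    corrected <- .applyBaseline(trace, bl)
    pass <- .detectAndFit(corrected, params)
    if (identical(sig(pass$events), sig(events))) {
      events <- pass$events
      converged <- TRUE
      break
    }
    events <- pass$events
  }
  if (!converged)
    warning("event set still changing after ", params@maxCycles,
            " reanalysis cycles; returning last iteration")
  list(corrected = corrected, events = events, baseline = bl,
       iterations = it, converged = converged)
}
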