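# Orchestration: full per-trace analysis and the headless equivalents of
# the interactive add/remove event corrections.

.eventsSchema <- function() {
  data.frame(id = character(0), t_trans_s = numeric(0),
             direction = character(0), a_trans_pA = numeric(0),
             conductance_pS = numeric(0), tc_trans_ms = numeric(0),
             A_pA = numeric(0), B_ms = numeric(0), C_pA = numeric(0),
             t_center_s = numeric(0), residual_rms_pA = numeric(0),
             fit_converged = logical(0), provenance = character(0),
             state_class = character(0), stringsAsFactors = FALSE)
}

.eventId <- function(traceId, t, fs, direction) {
  sprintf("%s:%d:%s", traceId, round(t * fs), substr(direction, 1L, 1L))
}

# Fit a set of event keys (t_trans_s, direction, provenance[, approx]) on a
# trace and assemble the event table.
.fitEvents <- function(trace, keys, params, traceId) {
  if (!nrow(keys)) return(.eventsSchema())
  keys <- keys[order(keys$t_trans_s), , drop = FALSE]
  fs <- trace@samplingRate
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    tk <- keys$t_trans_s[k]
    ld <- if ("approx" %in% names(keys)) keys$approx[k] else NULL
    if (!is.null(ld) && !is.finite(ld)) ld <- NULL
    fit <- fitTransition(trace, tk, halfwindow = params@fitHalfwindow,
                         neighbors = keys$t_trans_s[-k],
                         fitCenter = params@fitCenter, levelDiff = ld)
    data.frame(
      id = .eventId(traceId, tk, fs, keys$direction[k]), t_trans_s = tk,
      direction = keys$direction[k], a_trans_pA = fit$a_trans,
      conductance_pS = toConductance(fit$a_trans, trace@vm),
      tc_trans_ms = 1000 * fit$tc_trans, A_pA = fit$A, B_ms = 1000 * fit$B,
      C_pA = fit$C, t_center_s = fit$t_center,
      residual_rms_pA = fit$residual_rms, fit_converged = fit$converged,
      provenance = keys$provenance[k], state_class = NA_character_,
      stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$state_class <- classifyState(ev$conductance_pS, params@components)
  rownames(ev) <- NULL
  ev
}

# One full detection pass: median filter -> candidates -> TVD ->
# refinement -> erf fits -> classification.
.detectAndFit <- function(trace, params, traceId = "trace") {
  mf <- medianFilter(trace, params@tMF)
  cands <- detectCandidates(mf, params)
  if (!nrow(cands)) return(list(events = .eventsSchema(), tvd = NULL))
  tvd <- tvdDenoise(trace, params@tvdLambda, params@tvdIterations)
  rt <- vapply(seq_len(nrow(cands)), function(k)
    as.numeric(suppressWarnings(refineEventTime(
      tvd, cands$time_s[k], cands$direction[k], params@refineHalfwindow,
      params@refineStencil))), numeric(1))
  keys <- data.frame(t_trans_s = rt, direction = cands$direction,
                     provenance = "auto",
                     approx = cands$approx_amplitude_pA,
                     stringsAsFactors = FALSE)
  # two candidates refining onto the same edge: keep the larger amplitude
  kk <- paste(round(keys$t_trans_s * trace@samplingRate), keys$direction)
  keep <- !duplicated(kk)
  if (any(!keep)) {
    ord <- order(-abs(keys$approx))
    keep <- !duplicated(kk[ord])[order(ord)]
  }
  keys <- keys[keep, , drop = FALSE]
  list(events = .fitEvents(trace, keys, params, traceId), tvd = tvd)
}

# Canonical final state given the raw trace and the event keys only, so
# that manual edits compose deterministically (add-then-remove is the
# identity):  fit on raw -> idealized -> baseline -> corrected -> refit.
.finalize <- function(trace, keys, params, traceId, auditLog = list(),
                      iterations = 0L, converged = TRUE) {
  ev0 <- .fitEvents(trace, keys, params, traceId)
  if (nrow(ev0)) {
    # two rounds: the first baseline is estimated against amplitudes fitted
    # on the raw (drifting) trace; the second against corrected-trace fits
    events <- ev0
    for (round in 1:2) {
      ideal <- buildIdealized(trace, events)
      resid <- trace
      resid@current <- trace@current - ideal@current
      bl <- fitBaseline(resid, families = params@baselineFamilies)
      corrected <- .applyBaseline(trace, bl)
      events <- .fitEvents(corrected, keys, params, traceId)
    }
  } else {
    bl <- fitBaseline(trace, families = params@baselineFamilies)
    corrected <- .applyBaseline(trace, bl)
    events <- ev0
  }
  new("AnalysisResult", traceId = traceId, raw = trace,
      corrected = corrected,
      tvd = tvdDenoise(corrected, params@tvdLambda, params@tvdIterations),
      events = events, baseline = bl,
      summary = .gatingSummary(corrected, events, params),
      auditLog = auditLog, iterations = as.integer(iterations),
      converged = converged, params = params)
}

.keysOf <- function(events) {
  if (!nrow(events))
    return(data.frame(t_trans_s = numeric(0), direction = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  data.frame(t_trans_s = events$t_trans_s, direction = events$direction,
             provenance = events$provenance, stringsAsFactors = FALSE)
}

#' Run the full idealization pipeline on one trace
#'
#' Executes median filtering, derivative-threshold candidate detection,
#' TV denoising, transition-time refinement, erf transition fits, idealized
#' trace construction, baseline fitting and the iterative reanalysis loop,
#' then computes gating metrics.  Fully deterministic: identical inputs and
#' parameters give bit-identical event tables.  An empty event list is a
#' valid outcome (e.g. event-free control cells), with NPo = 0.
#'
#' @param trace a [ChannelTrace-class].
#' @param params an [AnalysisParams-class].
#' @param traceId identifier used in event ids; defaults to the trace's
#'   `traceId` metadata.
#' @return An [AnalysisResult-class].
#' @examples
#' sim <- simulateTrace(simConfig(duration = 6, seed = 42))
#' res <- analyzeTrace(sim$trace)
#' res
#' @export
analyzeTrace <- function(trace, params = analysisParams(), traceId = NULL) {
  stopifnot(is(trace, "ChannelTrace"))
  validObject(params)
  if (is.null(traceId))
    traceId <- if (!is.null(trace@metadata$traceId))
      trace@metadata$traceId else "trace"
  first <- .detectAndFit(trace, params, traceId)
  rr <- correctAndReanalyze(trace, params, firstPass = first$events)
  log <- list(list(action = "analyze", iterations = rr$iterations,
                   converged = rr$converged,
                   n_events = nrow(rr$events)))
  .finalize(trace, .keysOf(rr$events), params, traceId, auditLog = log,
            iterations = rr$iterations, converged = rr$converged)
}

#' Manually add a missed event
#'
#' Headless equivalent of the interactive "add" correction: searches for
#' the steepest sign-consistent derivative of the TV-denoised corrected
#' trace within `searchHalfwidth` samples of `approxTime`, fits the
#' transition there, and recomputes the idealized trace, baseline and all
#' metrics.  This is the supported route for sub-threshold events that the
#' 60 pS detection stage deliberately ignores.  If the search window
#' contains no sign-consistent derivative clearly above the noise floor
#' (5x the robust SD of the TVD derivative), the addition is refused with
#' an error and the result is unchanged.
#'
#' @param result an [AnalysisResult-class].
#' @param approxTime approximate event time (s), inside the trace.
#' @param direction `"opening"` or `"closing"`.
#' @param searchHalfwidth search half-window in samples (default 500).
#' @return A new [AnalysisResult-class] with the event inserted
#'   (provenance `"manual"`) and the edit appended to the audit log.
#' @export
addEvent <- function(result, approxTime, direction = c("opening", "closing"),
                     searchHalfwidth = 500) {
  addEvents(result, approxTime, match.arg(direction), searchHalfwidth)
}

# locate the steepest sign-consistent TVD derivative near a time, or NULL
.locateEdge <- function(result, approxTime, direction, searchHalfwidth) {
  tvd <- result@tvd
  n <- length(tvd@current)
  i0 <- round((approxTime - tvd@t0) * tvd@samplingRate) + 1
  if (i0 < 1 || i0 > n) stop("approxTime lies outside the trace")
  lo <- max(1L, i0 - as.integer(searchHalfwidth))
  hi <- min(n, i0 + as.integer(searchHalfwidth))
  h <- max(1L, round(result@params@refineStencil * tvd@samplingRate))
  ds <- wideDiff(tvd@current, h)[lo:hi] * stepSign(direction, tvd@vm)
  if (!length(ds) || max(ds) <= 0) return(NULL)
  tvd@t0 + (lo - 1L + which.max(ds) - 1L) / tvd@samplingRate
}

#' @rdname addEvent
#' @param times,directions vectors of approximate times (s) and directions
#'   for batch insertion (the whole batch is fitted and the result
#'   recomputed once).
#' @param minAmplitudeSE refusal criterion: the fitted transition must
#'   have `|a_trans|` above this multiple of its standard error (0
#'   disables the check, e.g. for scripted annotation at known times).
#' @export
addEvents <- function(result, times, directions, searchHalfwidth = 500,
                      minAmplitudeSE = 10) {
  stopifnot(is(result, "AnalysisResult"), length(times) == length(directions))
  keys <- .keysOf(result@events)
  log <- result@auditLog
  fs <- result@tvd@samplingRate
  added <- 0L
  for (k in seq_along(times)) {
    dir <- match.arg(directions[k], c("opening", "closing"))
    rt <- .locateEdge(result, times[k], dir, searchHalfwidth)
    refuse <- function(why)
      stop("no insertable ", dir, " near t = ", signif(times[k], 6),
           " s (", why, "); event not added")
    if (is.null(rt)) refuse("no sign-consistent derivative")
    if (minAmplitudeSE > 0) {
      fit <- tryCatch(
        fitTransition(result@corrected, rt,
                      halfwindow = result@params@fitHalfwindow,
                      neighbors = keys$t_trans_s,
                      fitCenter = result@params@fitCenter),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged)
        refuse("transition fit failed")
      nw <- round(diff(fit$window) * fs)
      se <- fit$residual_rms * sqrt(2 / max(nw, 2))
      if (abs(fit$a_trans) < minAmplitudeSE * se ||
          sign(fit$a_trans) != stepSign(dir, result@corrected@vm))
        refuse("no amplitude above the noise floor")
    }
    newId <- .eventId(result@traceId, rt, fs, dir)
    if (newId %in% result@events$id || any(
      abs(keys$t_trans_s - rt) < 0.5 / fs & keys$direction == dir))
      refuse("an identical event already exists")
    keys <- rbind(keys, data.frame(t_trans_s = rt, direction = dir,
                                   provenance = "manual",
                                   stringsAsFactors = FALSE))
    log <- c(log, list(list(action = "add", approx_time_s = times[k],
                            direction = dir,
                            search_halfwidth = searchHalfwidth,
                            min_amplitude_se = minAmplitudeSE,
                            refined_time_s = as.numeric(rt), id = newId)))
    added <- added + 1L
  }
  if (!added) return(result)
  .finalize(result@raw, keys, result@params, result@traceId, auditLog = log,
            iterations = result@iterations, converged = result@converged)
}

#' Annotate a result with events missed by automated detection
#'
#' Emulates the reviewer-intervention step of a semi-automated workflow on
#' simulated data: every ground-truth event without a matching detected
#' transition is inserted through the manual-add machinery at its true
#' location (so, unlike blind additions, the amplitude floor is disabled).
#' This removes the detection-threshold censoring from recovered event
#' sets, which matters when fitting the subconductance component of
#' conductance distributions.
#'
#' @param result an [AnalysisResult-class] from [analyzeTrace()].
#' @param truthEvents the ground-truth event table from [simulateTrace()].
#' @param tol matching tolerance in seconds (default 0.05).
#' @return An [AnalysisResult-class] including the annotated events.
#' @export
annotateMissedEvents <- function(result, truthEvents, tol = 0.05) {
  ev <- result@events
  missed <- vapply(seq_len(nrow(truthEvents)), function(k) {
    dir <- ifelse(truthEvents$direction[k] > 0, "opening", "closing")
    !any(ev$direction == dir &
           abs(ev$t_trans_s - truthEvents$time_s[k]) < tol)
  }, logical(1))
  if (!any(missed)) return(result)
  tm <- truthEvents$time_s[missed]
  dm <- ifelse(truthEvents$direction[missed] > 0, "opening", "closing")
  fs <- result@tvd@samplingRate
  hw <- max(10L, round(tol * fs))
  out <- tryCatch(
    addEvents(result, tm, dm, searchHalfwidth = hw, minAmplitudeSE = 0),
    error = function(e) NULL)
  if (!is.null(out)) return(out)
  # a refusal aborts a batch; fall back to one-at-a-time, skipping refusals
  out <- result
  for (k in seq_along(tm)) {
    res2 <- tryCatch(
      addEvents(out, tm[k], dm[k], searchHalfwidth = hw,
                minAmplitudeSE = 0),
      error = function(e) NULL)
    if (!is.null(res2)) out <- res2
  }
  out
}

#' Manually remove an erroneous event
#'
#' Headless equivalent of the interactive "delete" correction: removes the
#' event and recomputes the idealized trace, baseline and metrics.
#' Removing an event that [addEvent()] just inserted restores the original
#' result exactly.
#'
#' @param result an [AnalysisResult-class].
#' @param eventId an id from `events(result)$id`.
#' @return A new [AnalysisResult-class] without the event, edit logged.
#' @export
removeEvent <- function(result, eventId) {
  stopifnot(is(result, "AnalysisResult"))
  k <- match(eventId, result@events$id)
  if (is.na(k)) stop("unknown event id '", eventId, "'")
  keys <- .keysOf(result@events)[-k, , drop = FALSE]
  log <- c(result@auditLog,
           list(list(action = "remove", id = eventId)))
  .finalize(result@raw, keys, result@params, result@traceId, auditLog = log,
            iterations = result@iterations, converged = result@converged)
}

#' Replay logged manual edits onto a freshly analyzed trace
#'
#' Re-applies the add/remove entries of an audit log in order, so a final
#' result can be reproduced from the raw trace plus its log.
#'
#' @param trace the raw [ChannelTrace-class].
#' @param log an audit log from [auditLog()].
#' @param params the [AnalysisParams-class] used originally.
#' @return An [AnalysisResult-class].
#' @export
replayEdits <- function(trace, log, params = analysisParams()) {
  res <- analyzeTrace(trace, params)
  for (entry in log) {
    if (identical(entry$action, "add"))
      res <- addEvents(res, entry$approx_time_s, entry$direction,
                       entry$search_halfwidth,
                       minAmplitudeSE = if (is.null(entry$min_amplitude_se))
                         10 else entry$min_amplitude_se)
    else if (identical(entry$action, "remove"))
      res <- removeEvent(res, entry$id)
  }
  res
}
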