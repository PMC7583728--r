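# Text-based IO: traces as two-column delimited files, event tables as
# TSV, configurations and baseline reports as JSON.

#' Read a current trace from a two-column delimited file
#'
#' Expects columns `time_s` and `current_pA` (any delimiter `fread`
#' understands; a header is optional).  The sampling rate is inferred from
#' the median time step unless given.
#'
#' @param path file path.
#' @param vm step potential (mV) of the recording.
#' @param samplingRate sampling rate (Hz); inferred from the time column
#'   when NULL.
#' @param metadata named list of condition labels.
#' @return A [ChannelTrace-class].
#' @export
readTrace <- function(path, vm = 70, samplingRate = NULL,
                      metadata = list()) {
  d <- data.table::fread(path, header = "auto")
  if (ncol(d) < 2L) stop("expected two columns (time_s, current_pA)")
  tt <- as.numeric(d[[1L]]); cc <- as.numeric(d[[2L]])
  if (is.null(samplingRate)) {
    dt <- median(diff(tt))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate")
    samplingRate <- 1 / dt
  }
  channelTrace(cc, samplingRate = samplingRate, vm = vm, t0 = tt[1L],
               metadata = metadata)
}

#' Write a trace as two-column delimited text
#'
#' @param trace a [ChannelTrace-class].
#' @param path output path (TSV: `time_s`, `current_pA`).
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  data.table::fwrite(
    data.table::data.table(time_s = traceTimes(trace),
                           current_pA = trace@current),
    path, sep = "\t")
  invisible(path)
}

#' Write / read an event table
#'
#' Events travel as tab-separated text with the canonical columns
#' (`id`, `t_trans_s`, `direction`, `a_trans_pA`, `conductance_pS`,
#' `tc_trans_ms`, fit parameters, `provenance`, `state_class`).
#'
#' @param events event data.frame (from [events()]).
#' @param path file path.
#' @return `path` (write) or the event data.frame (read).
#' @export
writeEvents <- function(events, path) {
  data.table::fwrite(events, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Serialize a baseline model to a JSON report
#'
#' Emits the winning family with its coefficients plus the AIC of every
#' attempted family.
#'
#' @param model a [BaselineModel-class].
#' @param path output path; NULL returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
writeBaselineReport <- function(model, path = NULL) {
  rep <- list(
    family = model@family,
    params = as.list(model@params),
    rss = model@rss, aic = model@aic,
    families = lapply(model@allFits, function(f)
      list(params = as.list(f$params), rss = f$rss, aic = f$aic)),
    note = model@note)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Write / read a simulation configuration as JSON
#'
#' @param config a [SimConfig-class].
#' @param path file path.
#' @return `path` (write) or a [SimConfig-class] (read).
#' @export
writeSimConfig <- function(config, path) {
  l <- list(duration = config@duration, samplingRate = config@samplingRate,
            vm = config@vm, noiseSD = config@noiseSD,
            nChannels = config@nChannels,
            stateLevels = config@stateLevels,
            transitionRate = config@transitionRate, tcTau = config@tcTau,
            tcMax = config@tcMax,
            substateFraction = config@substateFraction,
            dwellMean = config@dwellMean, minSojourn = config@minSojourn,
            margin = config@margin,
            baselineFamily = config@baselineFamily,
            baselineParams = as.list(config@baselineParams),
            seed = if (is.na(config@seed)) NULL else config@seed)
  writeLines(jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  l <- jsonlite::fromJSON(path)
  bp <- unlist(l$baselineParams)
  simConfig(duration = l$duration, samplingRate = l$samplingRate,
            vm = l$vm, noiseSD = l$noiseSD, nChannels = l$nChannels,
            stateLevels = as.data.frame(l$stateLevels),
            transitionRate = l$transitionRate, tcTau = l$tcTau,
            tcMax = l$tcMax, substateFraction = l$substateFraction,
            dwellMean = l$dwellMean, minSojourn = l$minSojourn,
            margin = l$margin,
            baselineFamily = l$baselineFamily,
            baselineParams = if (length(bp)) bp else NULL,
            seed = if (is.null(l$seed)) NA else l$seed)
}

#' Export the gating summary of one or more analysis results
#'
#' @param results an [AnalysisResult-class] or list of them.
#' @param path optional TSV path.
#' @return data.frame, one row per trace.
#' @export
summaryTable <- function(results, path = NULL) {
  if (is(results, "AnalysisResult")) results <- list(results)
  rows <- lapply(results, function(r)
    cbind(data.frame(trace_id = r@traceId, stringsAsFactors = FALSE),
          r@summary,
          data.frame(baseline_family = r@baseline@family,
                     converged = r@converged)))
  out <- do.call(rbind, rows)
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out
}
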