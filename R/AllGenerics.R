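#' @rdname ChannelTrace-class
#' @param object,x a `ChannelTrace`.
#' @export
setGeneric("current", function(object) standardGeneric("current"))

#' @rdname ChannelTrace-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ChannelTrace-class
#' @export
setGeneric("vm", function(object) standardGeneric("vm"))

#' @rdname ChannelTrace-class
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname AnalysisResult-class
#' @param object an `AnalysisResult`.
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname AnalysisResult-class
#' @export
setGeneric("baselineModel", function(object) standardGeneric("baselineModel"))

#' @rdname AnalysisResult-class
#' @export
setGeneric("gatingSummary", function(object) standardGeneric("gatingSummary"))

#' @rdname AnalysisResult-class
#' @export
setGeneric("correctedTrace", function(object) standardGeneric("correctedTrace"))

#' @rdname AnalysisResult-class
#' @export
setGeneric("auditLog", function(object) standardGeneric("auditLog"))

#' @rdname ChannelTrace-class
#' @export
setMethod("current", "ChannelTrace", function(object) object@current)

#' @rdname ChannelTrace-class
#' @export
setMethod("samplingRate", "ChannelTrace", function(object) object@samplingRate)

#' @rdname ChannelTrace-class
#' @export
setMethod("vm", "ChannelTrace", function(object) object@vm)

#' @rdname ChannelTrace-class
#' @export
setMethod("traceTimes", "ChannelTrace", function(object)
  object@t0 + (seq_along(object@current) - 1) / object@samplingRate)

#' @rdname ChannelTrace-class
#' @export
setMethod("length", "ChannelTrace", function(x) length(x@current))

setMethod("show", "ChannelTrace", function(object) {
  cat(sprintf(
    "ChannelTrace: %d samples @ %g Hz (%.3f s), Vm = %g mV\n",
    length(object@current), object@samplingRate,
    length(object@current) / object@samplingRate, object@vm))
  if (length(object@current)) {
    cat(sprintf("  current [pA]: mean %.3f, range [%.3f, %.3f]\n",
                mean(object@current), min(object@current),
                max(object@current)))
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), unlist(object@metadata),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel: family '%s'\n", object@family))
  cat("  params:", paste(names(object@params),
                         signif(object@params, 5), sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  rss = %.4g pA^2, aic = %.4g\n", object@rss, object@aic))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "AnalysisResult", function(object) {
  cat(sprintf("AnalysisResult '%s': %d events, baseline '%s', %d cycle(s)%s\n",
              object@traceId, nrow(object@events), object@baseline@family,
              object@iterations,
              if (object@converged) "" else " [not converged]"))
  if (nrow(object@summary))
    cat(sprintf("  NPo = %.4g, transitions: %d (main %d / sub %d / uncl %d)\n",
                object@summary$npo, object@summary$n_transitions_total,
                object@summary$n_main, object@summary$n_substate,
                object@summary$n_unclassified))
  if (length(object@auditLog))
    cat(sprintf("  audit log: %d entr%s\n", length(object@auditLog),
                if (length(object@auditLog) == 1L) "y" else "ies"))
})

#' @rdname AnalysisResult-class
#' @export
setMethod("events", "AnalysisResult", function(object) object@events)

#' @rdname AnalysisResult-class
#' @export
setMethod("baselineModel", "AnalysisResult", function(object) object@baseline)

#' @rdname AnalysisResult-class
#' @export
setMethod("gatingSummary", "AnalysisResult", function(object) object@summary)

#' @rdname AnalysisResult-class
#' @export
setMethod("correctedTrace", "AnalysisResult", function(object) object@corrected)

#' @rdname AnalysisResult-class
#' @export
setMethod("auditLog", "AnalysisResult", function(object) object@auditLog)
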