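# Per-trace physiology metrics: conductance conversion, nominal open
# probability, transition counts by state class.

#' Convert a current step to a unitary conductance
#'
#' `gamma = delta_i / Vm`: a current step in pA divided by the step
#' potential in mV gives nS; reported in pS (1 pA/mV = 1000 pS).
#'
#' @param deltaI current step (pA); sign is ignored.
#' @param vm step potential (mV), non-zero.
#' @return Conductance in pS.
#' @examples
#' toConductance(15.19, 70)   # 217 pS
#' @export
toConductance <- function(deltaI, vm) {
  if (any(vm == 0)) stop("vm = 0: conductance undefined")
  abs(deltaI) / abs(vm) * 1000
}

#' Nominal open probability from a baseline-corrected trace
#'
#' NPo (number of active channels x open probability) is the cumulative
#' open time divided by the recording time, with the open-closed
#' discriminator set half-way between the closed and fully open levels
#' (`thresholdFraction = 0.5`).  Stacked multichannel openings count
#' k-fold: time spent above `k` open levels contributes `k` times.
#'
#' @param corrected a baseline-corrected [ChannelTrace-class] (closed level
#'   at about 0 pA).
#' @param openLevelPa fully open level in pA (> 0); typically the
#'   main-state conductance times `|vm| / 1000`.
#' @param thresholdFraction discriminator as a fraction of the open level.
#' @return One-row data.frame: `npo`, `open_time_s`, `recording_time_s`,
#'   `npo_reliable` (FALSE when the open level is within three noise SDs
#'   of the closed level, with a warning).
#' @export
computeNPo <- function(corrected, openLevelPa, thresholdFraction = 0.5) {
  stopifnot(is(corrected, "ChannelTrace"))
  if (!is.finite(openLevelPa) || openLevelPa <= 0)
    stop("openLevelPa must be positive")
  x <- corrected@current * sign(corrected@vm)
  n <- length(x)
  recT <- n / corrected@samplingRate
  noise <- mad(diff(x)) / sqrt(2)
  reliable <- openLevelPa > 3 * noise
  if (!reliable)
    warning("open level is within the noise floor; NPo unreliable")
  occ <- pmax(0, floor(x / openLevelPa + 1 - thresholdFraction))
  openT <- sum(occ) / corrected@samplingRate
  data.frame(npo = openT / recT, open_time_s = openT,
             recording_time_s = recT, npo_reliable = reliable)
}

#' Count transitions per trace and state class
#'
#' Tallies classified transitions and expresses the rate per the standard
#' 30 s recording window (scaled when the trace duration differs, for
#' comparability across protocols).
#'
#' @param events event data.frame with a `state_class` column (see
#'   [classifyState()]); may be empty.
#' @param components classification components (used to order classes).
#' @param recordingTime trace duration in seconds.
#' @param window reference window (s), default 30.
#' @return One-row data.frame: `n_transitions_total`, `n_main`,
#'   `n_substate`, `n_unclassified`, `transitions_per_30s`.
#' @export
countTransitions <- function(events, components = defaultComponents(),
                             recordingTime = 30, window = 30) {
  sc <- if (!is.null(events) && nrow(events)) events$state_class
    else character(0)
  nTot <- length(sc)
  data.frame(
    n_transitions_total = nTot,
    n_main = sum(sc == "main"),
    n_substate = sum(sc == "substate"),
    n_unclassified = sum(!sc %in% c("main", "substate")),
    transitions_per_30s = nTot * window / recordingTime)
}

# Full gating summary used by analyzeTrace / finalize.
.gatingSummary <- function(corrected, events, params) {
  openPS <- if (is.na(params@openLevelPS))
    max(params@components$mean) else params@openLevelPS
  npo <- suppressWarnings(
    computeNPo(corrected, psToPa(openPS, abs(corrected@vm)),
               params@thresholdFraction))
  recT <- length(corrected@current) / corrected@samplingRate
  cnt <- countTransitions(events, params@components, recordingTime = recT)
  cbind(npo, cnt)
}

#' Fold-change arithmetic between two gating conditions
#'
#' Reproduces the standard report arithmetic on per-trace mean transition
#' counts: main-state fold-change (reference/test), substate fold-change
#' (test/reference), overall transition-frequency fold (reference/test)
#' and the substate-fraction fold.  When the substate fractions are
#' supplied directly (e.g. as AUC-derived percentages) they are used for
#' the fraction fold; otherwise the count-based fractions are.
#'
#' @param reference,test named numeric vectors `c(main = , substate = )` of
#'   mean transitions per trace.
#' @param fracReference,fracTest optional substate fractions (0-1) of the
#'   two conditions, overriding the count-based fractions.
#' @return list: `main_fold`, `substate_fold`, `total_fold`,
#'   `substate_fraction_reference`, `substate_fraction_test`,
#'   `substate_fraction_fold`.
#' @examples
#' transitionFolds(c(main = 13.7, substate = 0.8),
#'                 c(main = 3.8, substate = 2.0),
#'                 fracReference = 0.053, fracTest = 0.347)
#' @export
transitionFolds <- function(reference, test, fracReference = NULL,
                            fracTest = NULL) {
  totR <- reference[["main"]] + reference[["substate"]]
  totT <- test[["main"]] + test[["substate"]]
  fR <- if (is.null(fracReference)) reference[["substate"]] / totR
    else fracReference
  fT <- if (is.null(fracTest)) test[["substate"]] / totT else fracTest
  list(main_fold = reference[["main"]] / test[["main"]],
       substate_fold = test[["substate"]] / reference[["substate"]],
       total_fold = totR / totT,
       substate_fraction_reference = fR,
       substate_fraction_test = fT,
       substate_fraction_fold = fT / fR)
}
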