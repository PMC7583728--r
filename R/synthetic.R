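# Ground-truth simulator: three-state gating with erf-shaped edges,
# stackable channels, Gaussian background noise and optional baseline drift.

.truncExp <- function(n, mean, upper) {
  # exponential truncated to (0, upper], sampled by inverse CDF
  u <- runif(n) * stats::pexp(upper, rate = 1 / mean)
  stats::qexp(u, rate = 1 / mean)
}

.truncNormPos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  g <- rnorm(n, mean, sd)
  bad <- which(g <= 0)
  while (length(bad)) {
    g[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[g[bad] <= 0]
  }
  g
}

# Per-channel renewal schedule: Poisson opening attempts while closed at a
# rate solved so that the expected transition rate over the whole trace
# matches config@transitionRate, then an exponential open dwell; the paired
# closing is truncated to the trace interior so levels are conserved.
.scheduleChannel <- function(config, channel) {
  T <- config@duration; m <- config@margin
  s0 <- config@minSojourn
  W <- T - 2 * m - s0                 # room for the final dwell
  R <- config@transitionRate
  if (R <= 0 || W <= 0) return(NULL)
  tau_d <- config@dwellMean
  # openings per channel in the window: R * T / 2  =>  mean closed wait
  wait <- 2 * W / (R * T) - tau_d
  if (wait <= s0) {
    warning("transitionRate too high for dwellMean/minSojourn; ",
            "closed gaps floored at minSojourn")
    wait <- s0 + .Machine$double.eps
  }
  sojourn <- function(mean) s0 + rexp(1, rate = 1 / (mean - s0))
  rows <- list()
  t <- m
  repeat {
    t_open <- t + sojourn(wait)
    if (t_open >= T - m - s0) break
    sub <- runif(1) < config@substateFraction
    sl <- config@stateLevels
    state <- if (sub) sl$label[which.min(sl$mean)] else sl$label[which.max(sl$mean)]
    i <- match(state, sl$label)
    g <- .truncNormPos(1, sl$mean[i], sl$sd[i])
    amp <- psToPa(g, config@vm)
    t_close <- min(t_open + sojourn(tau_d), T - m)
    tc <- .truncExp(2, config@tcTau, config@tcMax)
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = c(t_open, t_close), direction = c(1, -1),
      amplitude_pA = c(amp, -amp), conductance_pS = g, tc_ms = tc,
      state = state, channel = channel, stringsAsFactors = FALSE)
    t <- t_close
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.emptyTruthEvents <- function() {
  data.frame(time_s = numeric(0), direction = numeric(0),
             amplitude_pA = numeric(0), conductance_pS = numeric(0),
             tc_ms = numeric(0), state = character(0), channel = integer(0),
             stringsAsFactors = FALSE)
}

# Evaluate a drift family at times x (s).
.baselineFun <- function(family, p, x) {
  switch(family,
    none = rep(0, length(x)),
    constant = rep(p[["a"]], length(x)),
    linear = p[["a"]] * x + p[["b"]],
    single_exp = p[["a"]] * (1 - exp(-x / p[["b"]])) + p[["c"]],
    double_exp = p[["a"]] * (1 - exp(-x / p[["b"]])) +
      p[["c"]] * (1 - exp(-x / p[["d"]])) + p[["e"]],
    log = p[["a"]] * log(x + p[["c"]]) + p[["b"]],
    stop("unknown baseline family '", family, "'")
  )
}

#' Render a noiseless-or-noisy trace from a given event table
#'
#' Builds the piecewise-erf ideal signal for a set of transitions (each an
#' edge `amp/2 * (1 + erf((t - t0)/B))`), then adds i.i.d. Gaussian noise
#' and finally the configured baseline drift.  Used internally by
#' [simulateTrace()] and handy for constructing deterministic fixtures.
#'
#' @param config a [SimConfig-class]; supplies duration, sampling rate, vm,
#'   noise and drift settings.
#' @param events data.frame with columns `time_s`, `amplitude_pA` (signed
#'   step) and `tc_ms`; may be empty.
#' @return A [ChannelTrace-class].
#' @export
synthesizeTrace <- function(config, events = .emptyTruthEvents()) {
  validObject(config)
  n <- round(config@duration * config@samplingRate)
  times <- (seq_len(n) - 1) / config@samplingRate
  x <- numeric(n)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      x <- addErfEdge(x, times, events$time_s[k], events$amplitude_pA[k],
                      events$tc_ms[k] / 1000)
    }
  }
  if (config@noiseSD > 0)
    x <- x + rnorm(n, sd = psToPa(config@noiseSD, abs(config@vm)))
  drift <- .baselineFun(config@baselineFamily, config@baselineParams, times)
  channelTrace(x + drift, samplingRate = config@samplingRate, vm = config@vm)
}

#' Simulate one ground-truth-labelled gating trace
#'
#' Generates the gating schedule (per-channel Poisson opening attempts with
#' exponential open dwells), draws a conductance for every opening from the
#' targeted state Gaussian and a transition time constant for every edge
#' from a truncated exponential, renders erf-shaped edges, then adds
#' Gaussian background noise and finally the configured baseline drift.
#'
#' @param config a [SimConfig-class]; `config@seed` (when not NA) makes the
#'   trace reproducible.
#' @return A list with elements
#'   \describe{
#'     \item{trace}{the [ChannelTrace-class];}
#'     \item{truth}{a list with `events` (data.frame: `time_s`, `direction`
#'       +/-1, signed `amplitude_pA`, `conductance_pS`, `tc_ms`, `state`,
#'       `channel`) and `baseline` (the injected drift samples).}
#'   }
#' @examples
#' sim <- simulateTrace(simConfig(duration = 5, seed = 7))
#' nrow(sim$truth$events)
#' @export
simulateTrace <- function(config) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  ev <- lapply(seq_len(config@nChannels), function(ch)
    .scheduleChannel(config, ch))
  ev <- ev[!vapply(ev, is.null, logical(1))]
  events <- if (length(ev)) do.call(rbind, ev) else .emptyTruthEvents()
  if (nrow(events)) {
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  trace <- synthesizeTrace(config, events)
  n <- length(trace@current)
  times <- traceTimes(trace)
  drift <- .baselineFun(config@baselineFamily, config@baselineParams, times)
  list(trace = trace, truth = list(events = events, baseline = drift))
}

.deriveSeed <- function(seed, i) {
  # fixed splitting rule; stays below 2^31 - 1
  as.integer((as.numeric(seed) + i * 100003) %% 2147483629)
}

#' Simulate a cohort of independent traces
#'
#' Per-trace seeds are derived from the master seed by a fixed splitting
#' rule (`(seed + i * 100003) mod 2147483629`), so a cohort is reproducible
#' and each member equals `simulateTrace` run at its derived seed.
#'
#' @param config a [SimConfig-class] (its own `seed` field is ignored).
#' @param nTraces number of traces (>= 1).
#' @param seed master integer seed.
#' @return List of `nTraces` elements, each as from [simulateTrace()]; each
#'   trace carries `traceId` metadata.
#' @export
simulateCohort <- function(config, nTraces, seed) {
  if (nTraces < 1) stop("nTraces must be >= 1")
  lapply(seq_len(nTraces), function(i) {
    cfg <- config
    cfg@seed <- .deriveSeed(seed, i)
    sim <- simulateTrace(cfg)
    sim$trace@metadata$traceId <- sprintf("sim%03d", i)
    sim
  })
}
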