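# Internal numeric helpers shared across modules.

# Standard error function; erf(x) = 2*pnorm(x*sqrt(2)) - 1.
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Convert a conductance (pS) to a current step (pA) at step potential vm
# (mV): delta_i = g * vm / 1000 (pS * mV = 1e-3 pA).
psToPa <- function(g_ps, vm_mv) g_ps * vm_mv / 1000

# Add one erf-shaped edge of (signed) amplitude `amp` pA centred at time
# `t0_s` with time constant `b_s` (s) to `x` sampled at `times`.  The edge
# is rendered exactly as amp/2 * (1 + erf((t - t0)/B)): evaluated as an
# instantaneous step plus a local correction restricted to t0 +/- 8B, where
# erfc(8) ~ 1e-29 makes the truncation exact to machine precision.
addErfEdge <- function(x, times, t0_s, amp, b_s) {
  n <- length(x)
  dt <- times[2L] - times[1L]
  # step part: first sample with time >= t0
  i_on <- findInterval(t0_s, times, left.open = TRUE) + 1L
  if (i_on <= n) x[i_on:n] <- x[i_on:n] + amp
  if (b_s > 0) {
    half <- max(8 * b_s, 2 * dt)
    lo <- max(1L, findInterval(t0_s - half, times))
    hi <- min(n, findInterval(t0_s + half, times) + 1L)
    idx <- lo:hi
    tt <- times[idx] - t0_s
    x[idx] <- x[idx] + amp / 2 * (1 + erf(tt / b_s)) - amp * (tt >= 0)
  }
  x
}

# Centered boxcar mean with shrinking windows at the ends.
boxcarMean <- function(x, half) {
  n <- length(x)
  if (half < 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Symmetric-difference derivative estimate: d[i] = x[i+h] - x[i-h],
# clamped at the ends; returned per sample position.
wideDiff <- function(x, half) {
  n <- length(x)
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  x[hi] - x[lo]
}

# Total variation of a signal.
totalVariation <- function(x) sum(abs(diff(x)))

# Time of the first difference d[i] = x[i+1] - x[i], placed at the midpoint
# between the two samples.
diffTime <- function(trace, i) trace@t0 + (i - 0.5) / trace@samplingRate

# Nearest sample index for a time.
timeToIndex <- function(trace, t) {
  i <- round((t - trace@t0) * trace@samplingRate) + 1
  pmin(pmax(i, 1L), length(trace@current))
}
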