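# Shared oracles and fixture builders.  Everything here is independent of
# the implementation paths it checks.

erfRef <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Dense, direct evaluation of a piecewise-erf ideal signal (independent of
# the package's windowed edge renderer).
denseErfSignal <- function(times, events) {
  x <- numeric(length(times))
  for (k in seq_len(nrow(events))) {
    b <- events$tc_ms[k] / 1000
    a <- events$amplitude_pA[k]
    x <- x + if (b > 0) a / 2 * (1 + erfRef((times - events$time_s[k]) / b))
      else a * (times >= events$time_s[k])
  }
  x
}

# Exact optimality certificate for the TV proximal problem
#   min 1/2 sum((y-x)^2) + lambda sum(|diff(x)|):
# s = cumsum(x - y) must satisfy |s| <= lambda, s_n = 0, and
# s_i = lambda * sign(x[i+1] - x[i]) wherever x jumps.
tvKKTholds <- function(y, lambda, x, tol = 1e-7) {
  s <- cumsum(x - y)
  if (abs(s[length(s)]) > tol || any(abs(s) > lambda + tol)) return(FALSE)
  j <- diff(x)
  act <- which(abs(j) > 1e-9)
  length(act) == 0 || all(abs(s[act] - lambda * sign(j[act])) < 1e-5)
}

# Independent exact TV solve: box-constrained dual QP by L-BFGS-B.
tvDualQP <- function(y, lambda) {
  n <- length(y)
  Dt <- function(z) c(-z[1], if (n > 2) -diff(z) else NULL, z[n - 1])
  o <- optim(rep(0, n - 1), function(z) 0.5 * sum((Dt(z) - y)^2),
             function(z) diff(Dt(z) - y), method = "L-BFGS-B",
             lower = -lambda, upper = lambda,
             control = list(maxit = 50000, factr = 1))
  y - Dt(o$par)
}

# Naive centred running median with shrinking edge windows and midpoint of
# the two central order statistics for even counts (direct definition).
naiveRunMedian <- function(x, w) {
  n <- length(x)
  hl <- (w - 1) %/% 2
  hr <- w - 1 - hl
  vapply(seq_len(n), function(i) {
    win <- sort(x[max(1, i - hl):min(n, i + hr)])
    m <- length(win)
    if (m %% 2 == 1) win[(m + 1) / 2] else mean(win[m / 2 + 0:1])
  }, numeric(1))
}

# Match detected events to ground truth by time and direction.
matchEvents <- function(ev, truth, tol_s = 0.05) {
  used <- rep(FALSE, nrow(ev))
  idx <- integer(nrow(truth))
  for (k in seq_len(nrow(truth))) {
    dir <- ifelse(truth$direction[k] > 0, "opening", "closing")
    j <- which(!used & ev$direction == dir &
                 abs(ev$t_trans_s - truth$time_s[k]) < tol_s)
    idx[k] <- if (length(j)) j[which.min(abs(ev$t_trans_s[j] -
                                               truth$time_s[k]))] else NA
    if (!is.na(idx[k])) used[idx[k]] <- TRUE
  }
  idx
}

# Simulated trace with an extra sub-threshold (default 50 pS) event pair
# hidden in a clean stretch, for manual-add workflows.
mkWithHidden <- function(seed = 59, hidden_ps = 50) {
  cfg <- simConfig(duration = 12, seed = seed)
  sim <- simulateTrace(cfg)
  ev <- sim$truth$events
  # first stretch clear of true events around both the pulse edges
  cand <- seq(2, 10, by = 0.2)
  free <- cand[vapply(cand, function(a)
    !any(abs(ev$time_s - a) < 1.2) && !any(abs(ev$time_s - (a + 0.8)) < 0.4),
    logical(1))]
  stopifnot(length(free) > 0)
  at <- free[1]
  amp <- hidden_ps * 70 / 1000
  extra <- data.frame(time_s = c(at, at + 0.8),
                      direction = c(1, -1),
                      amplitude_pA = c(amp, -amp),
                      conductance_pS = hidden_ps, tc_ms = 3,
                      state = "substate", channel = 99L)
  all <- rbind(ev, extra)[order(c(ev$time_s, extra$time_s)), ]
  set.seed(seed)
  list(trace = synthesizeTrace(cfg, all), at = at)
}

# A quiet config for fast unit tests (short trace, no drift).
quickConfig <- function(...) {
  simConfig(duration = 10, ...)
}

analyzeQuiet <- function(trace, params = analysisParams())
  suppressWarnings(analyzeTrace(trace, params))
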