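mkStepTrace <- function(g_ps, vm = 70, n = 8000, at = 4000, noise = 0,
                        fs = 4000) {
  x <- c(rep(0, at), rep(g_ps * vm / 1000, n - at))
  if (noise > 0) x <- x + rnorm(n, sd = noise * abs(vm) / 1000)
  channelTrace(x, samplingRate = fs, vm = vm)
}

test_that("flat traces yield no candidates", {
  tr <- channelTrace(rep(0, 4000))
  expect_identical(nrow(detectCandidates(medianFilter(tr, 0.3))), 0L)
})

test_that("a clean 217 pS step gives exactly one opening; 40 pS stays below threshold", {
  big <- detectCandidates(medianFilter(mkStepTrace(217), 0.3))
  expect_identical(nrow(big), 1L)
  expect_identical(big$direction, "opening")
  expect_equal(big$approx_amplitude_pA, 15.19, tolerance = 0.01)

  small <- detectCandidates(medianFilter(mkStepTrace(40), 0.3))
  expect_identical(nrow(small), 0L)
})

test_that("vm = 0 is a configuration error", {
  tr <- channelTrace(rep(0, 1000), vm = 0)
  expect_error(detectCandidates(medianFilter(tr, 0.1)), "vm = 0")
})

test_that("negative step potentials flip the sign convention", {
  tr <- mkStepTrace(217, vm = -70)   # current steps negative-going
  cand <- detectCandidates(medianFilter(tr, 0.3))
  expect_identical(cand$direction, "opening")
  expect_lt(cand$approx_amplitude_pA, 0)
})

test_that("raising the threshold never increases the candidate count", {
  set.seed(11)
  sim <- simulateTrace(simConfig(duration = 15, seed = 321))
  mf <- medianFilter(sim$trace, 0.3)
  counts <- vapply(c(30, 60, 90, 150, 250), function(th)
    nrow(detectCandidates(mf, analysisParams(thresholdPS = th))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("refinement recovers ideal step times to within a sample", {
  tr <- mkStepTrace(217)
  tvd <- tvdDenoise(tr)
  stepTime <- 4000 / 4000               # first high sample
  rt <- refineEventTime(tvd, stepTime + 0.2, "opening")  # 200 ms offset
  expect_lt(abs(as.numeric(rt) - stepTime), 1.5 / 4000)
  expect_true(attr(rt, "refined"))
})

test_that("the steeper of two same-sign edges inside the window is selected", {
  cfg <- simConfig(duration = 4, noiseSD = 0, transitionRate = 0)
  ev <- data.frame(time_s = c(1.9, 2.1), amplitude_pA = c(8, 8),
                   tc_ms = c(40, 2))    # second edge is much steeper
  tr <- synthesizeTrace(cfg, ev)
  tvd <- tvdDenoise(tr)
  rt <- as.numeric(refineEventTime(tvd, 2.0, "opening", halfwindow = 0.3))
  # exhaustive argmax oracle over the window on the same stencil
  h <- round(0.010 * 4000)
  x <- current(tvd)
  idx <- which(traceTimes(tvd) >= 1.7 & traceTimes(tvd) <= 2.3)
  d <- x[pmin(idx + h, length(x))] - x[pmax(idx - h, 1)]
  tOracle <- traceTimes(tvd)[idx[which.max(d)]]
  expect_equal(rt, tOracle, tolerance = 1e-9)
  expect_lt(abs(rt - 2.1), 0.01)
})

test_that("candidates without a sign-consistent derivative are kept unrefined", {
  tr <- mkStepTrace(217)                 # opening only
  tvd <- tvdDenoise(tr)
  expect_warning(rt <- refineEventTime(tvd, 1, "closing"), "sign-consistent")
  expect_false(attr(rt, "refined"))
  expect_identical(as.numeric(rt), 1)
})

test_that("refined times deviate < 2 ms RMS from truth at zero noise, tc <= 20 ms", {
  cfg <- simConfig(duration = 20, noiseSD = 0, transitionRate = 0)
  set.seed(77)
  times <- seq(1, 19, by = 1.5)
  ev <- data.frame(time_s = times,
                   amplitude_pA = rep(c(15, -15), length.out = length(times)),
                   tc_ms = runif(length(times), 0.5, 20))
  # keep levels physical: alternate open/close
  tr <- synthesizeTrace(cfg, ev)
  tvd <- tvdDenoise(tr)
  err <- vapply(seq_len(nrow(ev)), function(k) {
    dir <- ifelse(ev$amplitude_pA[k] > 0, "opening", "closing")
    as.numeric(refineEventTime(tvd, ev$time_s[k] + 0.05, dir)) - ev$time_s[k]
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.002)
})
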