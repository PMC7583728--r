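test_that("no events give an all-zero idealized trace", {
  tr <- channelTrace(rnorm(1000))
  id <- buildIdealized(tr, NULL)
  expect_identical(current(id), rep(0, 1000))
})

test_that("an opening/closing pair of equal amplitude is a rectangular pulse", {
  tr <- channelTrace(rep(0, 8000))
  ev <- data.frame(t_trans_s = c(0.5, 1.5), a_trans_pA = c(15, -15),
                   tc_trans_ms = c(0, 0))
  id <- current(buildIdealized(tr, ev))
  expect_equal(id[traceTimes(tr) < 0.5], rep(0, sum(traceTimes(tr) < 0.5)))
  inside <- traceTimes(tr) > 0.51 & traceTimes(tr) < 1.49
  expect_equal(id[inside], rep(15, sum(inside)))
  expect_equal(id[traceTimes(tr) > 1.51],
               rep(0, sum(traceTimes(tr) > 1.51)))
})

test_that("level conservation: sum of signed amplitudes of a pair is ~0 and
           negative excursions are warned about", {
  tr <- channelTrace(rep(0, 4000))
  bad <- data.frame(t_trans_s = c(0.3, 0.6), a_trans_pA = c(-12, 12),
                    tc_trans_ms = c(0, 0))
  expect_warning(buildIdealized(tr, bad), "below the closed state")
})

test_that("residual after subtracting truth-built idealized trace is noise plus drift", {
  cfg <- simConfig(duration = 15, seed = 60, baselineFamily = "linear")
  sim <- simulateTrace(cfg)
  tru <- sim$truth$events
  ev <- data.frame(t_trans_s = tru$time_s, a_trans_pA = tru$amplitude_pA,
                   tc_trans_ms = tru$tc_ms, t_center_s = tru$time_s)
  id <- buildIdealized(sim$trace, ev)
  resid <- current(sim$trace) - current(id) - sim$truth$baseline
  expect_equal(sd(resid), 30 * 70 / 1000, tolerance = 0.1)
})

test_that("a linear ramp is identified and its slope recovered", {
  set.seed(8)
  fs <- 1000; tt <- (0:14999) / fs
  y <- 1.3 * tt + 4 + rnorm(length(tt), sd = 0.5)
  bl <- fitBaseline(channelTrace(y, samplingRate = fs))
  # closed-form least-squares oracle
  slopeHat <- unname(coef(lm(y ~ tt))[2])
  fit <- bl@allFits[["linear"]]
  expect_equal(unname(fit$params[["a"]]), slopeHat, tolerance = 0.02)
  expect_equal(unname(fit$params[["a"]]), 1.3, tolerance = 0.02 * 1.3)
})

test_that("a noiseless single exponential is recovered near-exactly", {
  fs <- 1000; tt <- (0:19999) / fs
  y <- 50 * (1 - exp(-tt / 5)) + 2
  bl <- fitBaseline(channelTrace(y, samplingRate = fs))
  expect_identical(bl@family, "single_exp")
  expect_equal(unname(bl@params[c("a", "b", "c")]), c(50, 5, 2),
               tolerance = 1e-4)
})

test_that("flat residuals leave the corrected trace unchanged", {
  set.seed(12)
  y <- rnorm(8000, sd = 2)
  tr <- channelTrace(y, samplingRate = 1000)
  bl <- fitBaseline(tr)
  drift <- baselineValues(bl, traceTimes(tr))
  expect_lt(max(drift) - min(drift), 0.5)   # well below noise
})

test_that("baseline fitting is idempotent", {
  set.seed(13)
  fs <- 1000; tt <- (0:14999) / fs
  y <- 40 * (1 - exp(-tt / 4)) + rnorm(length(tt), sd = 2)
  tr <- channelTrace(y, samplingRate = fs)
  bl1 <- fitBaseline(tr)
  corr <- channelTrace(y - baselineValues(bl1, tt), samplingRate = fs)
  bl2 <- fitBaseline(corr)
  d2 <- baselineValues(bl2, tt)
  expect_lt(max(d2) - min(d2), 0.4)         # non-constant part << noise SD
})

test_that("short residuals are rejected", {
  expect_error(fitBaseline(channelTrace(rnorm(20))), "residual too short")
})

test_that("reanalysis reaches a fixed point on drift-free traces", {
  sim <- simulateTrace(simConfig(duration = 12, seed = 90))
  out <- suppressWarnings(correctAndReanalyze(sim$trace))
  expect_true(out$converged)
  expect_lte(out$iterations, 2L)
  expect_identical(nrow(out$events),
                   nrow(suppressWarnings(correctAndReanalyze(
                     sim$trace))$events))
})

test_that("drift-only traces are corrected to zero-mean noise", {
  cfg <- simConfig(duration = 12, transitionRate = 0,
                   baselineFamily = "double_exp", seed = 41)
  sim <- simulateTrace(cfg)
  out <- suppressWarnings(correctAndReanalyze(sim$trace))
  expect_identical(nrow(out$events), 0L)
  noiseSD <- 30 * 70 / 1000
  expect_lt(abs(mean(current(out$corrected))), 0.1 * noiseSD)
})
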