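test_that("invalid configuration fields raise errors naming the field", {
  expect_error(simConfig(duration = -1), "duration")
  expect_error(simConfig(substateFraction = 1.5), "substateFraction")
  expect_error(simConfig(vm = 0), "vm")
  expect_error(simConfig(noiseSD = -3), "noiseSD")
  expect_error(simConfig(stateLevels = data.frame(
    label = "main", mean = -217, sd = 66)), "conductances")
})

test_that("no event sources yield a constant-zero trace and no events", {
  sim <- simulateTrace(simConfig(duration = 2, transitionRate = 0,
                                 noiseSD = 0, seed = 1))
  expect_identical(max(abs(current(sim$trace))), 0)
  expect_identical(nrow(sim$truth$events), 0L)
})

test_that("a single 217 pS opening at +70 mV spans gamma * Vm = 15.19 pA", {
  cfg <- simConfig(duration = 2, transitionRate = 0, noiseSD = 0)
  ev <- data.frame(time_s = 1, amplitude_pA = 217 * 70 / 1000, tc_ms = 5)
  tr <- synthesizeTrace(cfg, ev)
  expect_equal(max(current(tr)) - min(current(tr)), 15.19, tolerance = 1e-12)
})

test_that("zero-noise traces equal the piecewise-erf ideal to machine precision", {
  cfg <- simConfig(duration = 8, noiseSD = 0, seed = 42)
  sim <- simulateTrace(cfg)
  ref <- denseErfSignal(traceTimes(sim$trace), sim$truth$events)
  expect_lt(max(abs(current(sim$trace) - ref)), 1e-10)
})

test_that("ground-truth amplitudes equal drawn conductance times Vm", {
  sim <- simulateTrace(simConfig(duration = 20, seed = 9, vm = 55))
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  expect_equal(abs(ev$amplitude_pA), ev$conductance_pS * 55 / 1000,
               tolerance = 1e-12)
})

test_that("simulation is reproducible and cohorts derive per-trace seeds", {
  cfg <- simConfig(duration = 5, seed = 123)
  a <- simulateTrace(cfg); b <- simulateTrace(cfg)
  expect_identical(current(a$trace), current(b$trace))
  expect_identical(a$truth$events, b$truth$events)

  co1 <- simulateCohort(simConfig(duration = 5), 3, seed = 77)
  co2 <- simulateCohort(simConfig(duration = 5), 3, seed = 77)
  expect_identical(lapply(co1, function(s) current(s$trace)),
                   lapply(co2, function(s) current(s$trace)))
  # single-member cohort equals simulateTrace at the derived seed
  cfg1 <- simConfig(duration = 5, seed = patchseg:::.deriveSeed(77, 1))
  solo <- simulateTrace(cfg1)
  expect_identical(current(co1[[1]]$trace), current(solo$trace))
})

test_that("event counts match the configured transition rate", {
  # rate 1/s over 30 s: mean transitions per trace within 3 SE of 30
  # (schedule statistics are sampling-rate independent, so simulate coarse)
  cfg <- simConfig(duration = 30, samplingRate = 200, transitionRate = 1,
                   noiseSD = 0)
  counts <- vapply(seq_len(200), function(i) {
    cfg@seed <- patchseg:::.deriveSeed(5000, i)
    nrow(simulateTrace(cfg)$truth$events)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 30), 3 * se)
})

test_that("substate share of ground-truth events follows the configured fraction", {
  cfg <- simConfig(duration = 30, samplingRate = 200,
                   substateFraction = 0.347)
  ev <- do.call(rbind, lapply(simulateCohort(cfg, 50, seed = 31),
                              function(s) s$truth$events))
  op <- ev[ev$direction > 0, ]          # one state draw per gating cycle
  n <- nrow(op)
  k <- sum(op$state == "substate")
  ci <- qbinom(c(0.005, 0.995), n, 0.347)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("empirical noise SD matches the configured value", {
  cfg <- simConfig(duration = 30, transitionRate = 0, noiseSD = 30,
                   seed = 8)
  x <- current(simulateTrace(cfg)$trace)   # 120k samples, events-free
  expect_equal(sd(x), 30 * 70 / 1000, tolerance = 0.05)
})

test_that("channel occupancy stays within [0, nChannels]", {
  sim <- suppressWarnings(
    simulateTrace(simConfig(duration = 30, samplingRate = 500,
                            nChannels = 3, transitionRate = 2,
                            noiseSD = 0, seed = 4)))
  ev <- sim$truth$events
  for (ch in unique(ev$channel)) {
    lev <- cumsum(ev$direction[ev$channel == ch])
    expect_true(all(lev %in% 0:1))
  }
  lev <- cumsum(ev$direction)
  expect_true(all(lev >= 0 & lev <= 3))
})
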