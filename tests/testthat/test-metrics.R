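test_that("conductance conversion follows gamma = delta_i / Vm", {
  expect_equal(toConductance(15.19, 70), 217)
  expect_identical(toConductance(0, 70), 0)
  expect_equal(toConductance(2 * 7.7, 70), 2 * toConductance(7.7, 70))
  expect_equal(toConductance(-15.19, -70), 217)  # magnitudes only
  expect_error(toConductance(1, 0), "vm = 0")
})

test_that("NPo is 0 on closed traces and 1 at the open level", {
  flat <- channelTrace(rep(0, 4000))
  expect_identical(computeNPo(flat, 15.19)$npo, 0)
  open <- channelTrace(rep(15.19, 4000))
  expect_identical(computeNPo(open, 15.19)$npo, 1)
})

test_that("NPo equals the true occupancy for a known open interval", {
  # one channel open exactly 9 s of 30 s, zero noise
  cfg <- simConfig(duration = 30, noiseSD = 0, transitionRate = 0)
  ev <- data.frame(time_s = c(10, 19), amplitude_pA = c(15.19, -15.19),
                   tc_ms = c(1, 1))
  tr <- synthesizeTrace(cfg, ev)
  out <- computeNPo(tr, 15.19)
  expect_equal(out$npo, 9 / 30, tolerance = 1e-3)
  expect_equal(out$open_time_s, 9, tolerance = 0.05)
})

test_that("stacked openings count k-fold and negative vm works", {
  cfg <- simConfig(duration = 10, noiseSD = 0, transitionRate = 0)
  ev <- data.frame(time_s = c(2, 4, 6, 8),
                   amplitude_pA = c(15, 15, -15, -15),
                   tc_ms = rep(0.5, 4))
  tr <- synthesizeTrace(cfg, ev)       # occupancy 0,1,2,1,0
  out <- computeNPo(tr, 15)
  expect_equal(out$npo, (2 + 2 * 2 + 2) / 10, tolerance = 1e-2)

  cfgN <- simConfig(duration = 10, noiseSD = 0, transitionRate = 0, vm = -70)
  evN <- ev; evN$amplitude_pA <- -ev$amplitude_pA
  trN <- synthesizeTrace(cfgN, evN)
  expect_equal(computeNPo(trN, 15)$npo, out$npo, tolerance = 1e-6)
})

test_that("an open level in the noise floor is flagged unreliable", {
  set.seed(2)
  tr <- channelTrace(rnorm(4000, sd = 2))
  expect_warning(out <- computeNPo(tr, 0.5), "unreliable")
  expect_false(out$npo_reliable)
})

test_that("transition counting tallies classes and scales to 30 s", {
  ev <- data.frame(state_class = rep("main", 10))
  out <- countTransitions(ev, recordingTime = 30)
  expect_identical(out$n_main, 10L)
  expect_identical(out$n_substate, 0L)
  expect_identical(out$transitions_per_30s, 10)

  empty <- countTransitions(NULL, recordingTime = 30)
  expect_identical(empty$n_transitions_total, 0L)
  expect_identical(empty$transitions_per_30s, 0)

  # rate normalization for other durations
  out15 <- countTransitions(ev, recordingTime = 15)
  expect_identical(out15$transitions_per_30s, 20)

  # additivity across concatenated traces
  a <- countTransitions(ev, recordingTime = 30)
  b <- countTransitions(data.frame(state_class = rep("substate", 4)),
                        recordingTime = 30)
  both <- countTransitions(data.frame(
    state_class = c(rep("main", 10), rep("substate", 4))),
    recordingTime = 60)
  expect_identical(both$n_transitions_total,
                   a$n_transitions_total + b$n_transitions_total)
  expect_identical(both$n_main + both$n_substate, 14L)
})

test_that("fold-change report reproduces the printed cohort arithmetic", {
  f <- transitionFolds(c(main = 13.7, substate = 0.8),
                       c(main = 3.8, substate = 2.0),
                       fracReference = 0.053, fracTest = 0.347)
  expect_equal(round(f$main_fold, 1), 3.6)
  expect_equal(f$substate_fold, 2.5)
  expect_equal(round(f$total_fold, 1), 2.5)
  expect_equal(signif(f$substate_fraction_fold, 2), 6.5)
  # count-based fractions when none are supplied
  g <- transitionFolds(c(main = 13.7, substate = 0.8),
                       c(main = 3.8, substate = 2.0))
  expect_equal(g$substate_fraction_reference, 0.8 / 14.5)
  expect_equal(g$substate_fraction_test, 2.0 / 5.8)
})
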