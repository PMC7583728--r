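edgeTrace <- function(A = 10, B_ms = 5, C = 0, t0 = 1, duration = 2,
                      noise = 0, fs = 4000, vm = 70, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(duration * fs) - 1) / fs
  x <- A * erfRef((tt - t0) / (B_ms / 1000)) + C
  if (noise > 0) x <- x + rnorm(length(x), sd = noise)
  channelTrace(x, samplingRate = fs, vm = vm)
}

test_that("noiseless erf edges are recovered to 1e-6 relative", {
  fit <- fitTransition(edgeTrace(A = 10, B_ms = 5), 1)
  expect_equal(fit$a_trans, 20, tolerance = 1e-6)
  expect_equal(fit$tc_trans, 0.005, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$residual_rms, 1e-6)
  # with the center fixed at the exact time (the reference 3-parameter fit)
  fit3 <- fitTransition(edgeTrace(A = 10, B_ms = 5), 1, fitCenter = FALSE)
  expect_equal(fit3$a_trans, 20, tolerance = 1e-6)
  expect_equal(fit3$tc_trans, 0.005, tolerance = 1e-6)
})

test_that("the fit is symmetric: negating the trace negates A, keeps B", {
  up <- fitTransition(edgeTrace(A = 7, B_ms = 3), 1)
  tr <- edgeTrace(A = 7, B_ms = 3)
  tr@current <- -tr@current
  dn <- fitTransition(tr, 1)
  expect_equal(dn$A, -up$A, tolerance = 1e-8)
  expect_equal(dn$B, up$B, tolerance = 1e-8)
})

test_that("amplitude recovery is unbiased under recording noise", {
  # 200 replicates at 30 pS-equivalent noise (2.1 pA at 70 mV)
  a <- vapply(seq_len(200), function(i)
    fitTransition(edgeTrace(A = 10, B_ms = 5, noise = 2.1, fs = 1000,
                            seed = 4000 + i), 1)$a_trans, numeric(1))
  expect_equal(mean(a), 20, tolerance = 0.01)
})

test_that("a second jump in the window is excluded by readjustment", {
  cfg <- simConfig(duration = 3, noiseSD = 0, transitionRate = 0)
  ev <- data.frame(time_s = c(1, 1.08), amplitude_pA = c(12, 9),
                   tc_ms = c(4, 4))
  tr <- synthesizeTrace(cfg, ev)
  fit <- fitTransition(tr, 1, neighbors = 1.08)
  # oracle: fit on a manually truncated window that stops at the midpoint
  expect_lte(fit$window[2], 1.042)
  expect_equal(fit$a_trans, 12, tolerance = 0.02 * 12)
})

test_that("events closer than 20 samples are fitted jointly", {
  cfg <- simConfig(duration = 3, noiseSD = 0, transitionRate = 0)
  ev <- data.frame(time_s = c(1, 1.003), amplitude_pA = c(12, 9),
                   tc_ms = c(1.5, 1.5))
  tr <- synthesizeTrace(cfg, ev)
  fit <- fitTransition(tr, 1, neighbors = 1.003)
  expect_true(fit$joint)
  expect_equal(fit$a_trans, 12, tolerance = 0.05 * 12)
})

test_that("too-small windows after readjustment are an error", {
  tr <- edgeTrace()
  expect_error(fitTransition(tr, 1, halfwindow = 0.0005), "10 samples")
})

test_that("state classification follows the one-SD interval rule", {
  comp <- defaultComponents()
  expect_identical(classifyState(c(217, 79, 140), comp),
                   c("main", "substate", "unclassified"))
  # overlapping components: nearest mean in SD units wins
  comp2 <- data.frame(label = c("a", "b"), mean = c(100, 140), sd = c(30, 30))
  expect_identical(classifyState(115, comp2), "a")
  expect_identical(classifyState(125, comp2), "b")
  expect_error(classifyState(100, comp[0, ]), "non-empty")
})
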