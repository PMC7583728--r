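test_that("a single Gaussian component is recovered at cohort scale", {
  set.seed(210)
  g <- rnorm(2000, 217, 66)
  fit <- fitConductanceHistogram(g, 1)
  expect_lt(abs(fit$mean - 217), 3)
  expect_lt(abs(fit$sd - 66), 5)
})

test_that("two components are recovered from a bimodal mixture", {
  set.seed(22)
  g <- c(rnorm(1300, 217, 66), rnorm(700, 80, 28))
  fit <- fitConductanceHistogram(g, 2)
  expect_identical(nrow(fit), 2L)
  expect_lt(abs(fit$mean[1] - 80), 6)
  expect_lt(abs(fit$sd[1] - 28), 6)
  expect_lt(abs(fit$mean[2] - 217), 10)
  expect_lt(abs(fit$sd[2] - 66), 10)
})

test_that("histogram and MLE routes agree on well-separated mixtures", {
  set.seed(23)
  g <- c(rnorm(1500, 217, 50), rnorm(1500, 80, 20))
  a <- fitConductanceHistogram(g, 2, method = "histogram")
  b <- fitConductanceHistogram(g, 2, method = "mle")
  expect_equal(a$mean, b$mean, tolerance = 0.05 * 217)
})

test_that("degenerate and undersized inputs are handled", {
  expect_error(fitConductanceHistogram(rnorm(10, 217, 66)), "at least 30")
  expect_error(fitConductanceHistogram(rnorm(40, 217, 66), 2), "at least 60")
  expect_warning(fit <- fitConductanceHistogram(rep(100, 50)), "identical")
  expect_true(attr(fit, "degenerate"))
  expect_identical(fit$sd, 10)
})

test_that("Gaussian histogram fitting is location-equivariant", {
  set.seed(24)
  g <- rnorm(1000, 217, 66)
  f0 <- fitConductanceHistogram(g, 1)
  f1 <- fitConductanceHistogram(g + 200, 1)   # exact multiple of bin width
  expect_equal(f1$mean - f0$mean, 200, tolerance = 1e-6)
  expect_equal(f1$sd, f0$sd, tolerance = 1e-6)
})

test_that("substate ratios and fold-changes follow the AUC arithmetic", {
  r <- substateRatio(0.347, 0.053)
  expect_equal(signif(r$fold_vs_reference, 2), 6.5)
  expect_equal(substateRatio(0.2, 0.2)$fold_vs_reference, 1)
  expect_warning(r0 <- substateRatio(0.3, 0), "overflows")
  expect_identical(r0$fold_vs_reference, Inf)
  expect_true(r0$flagged)

  comps <- data.frame(label = c("c1", "c2"), mean = c(80, 217),
                      sd = c(28, 66), amplitude = c(0.8, 1),
                      auc = c(0.8 * 28, 66) * sqrt(2 * pi))
  rc <- substateRatio(comps)
  expect_equal(rc$ratio, comps$auc[1] / sum(comps$auc))
  expect_gte(rc$ratio, 0); expect_lte(rc$ratio, 1)
  # AUC ratio is invariant to the normalization constant
  comps2 <- comps; comps2$auc <- comps2$auc * 7.3
  expect_equal(substateRatio(comps2)$ratio, rc$ratio)
})

test_that("a missing reference substate uses the scaled template, flagged", {
  set.seed(25)
  gRef <- rnorm(500, 217, 66)
  tmpl <- data.frame(mean = 80, sd = 28)
  sc <- scaleSubstateTemplate(tmpl, gRef)
  expect_gte(sc$amplitude, 0)
  refMain <- fitConductanceHistogram(gRef, 1)
  test <- data.frame(label = c("c1", "c2"), mean = c(80, 217),
                     sd = c(28, 66), amplitude = c(0.9, 1),
                     auc = c(0.9 * 28, 66) * sqrt(2 * pi))
  out <- substateRatio(test, refMain, referenceSub = sc)
  expect_true(out$flagged)
  expect_true(is.finite(out$fold_vs_reference))
})

test_that("monoexponential cohorts select mono and recover tau", {
  set.seed(26)
  f <- fitTcDistribution(rexp(1656, 1 / 5.2))
  expect_identical(f$n_components, 1L)
  expect_lt(abs(f$taus - 5.2) / 5.2, 0.05)
})

test_that("biexponential mixtures select bi and recover the slow component", {
  set.seed(27)
  tc <- c(rexp(194, 1 / 5.2), rexp(452, 1 / 17.3))
  f <- fitTcDistribution(tc)
  expect_identical(f$n_components, 2L)
  expect_lt(abs(f$taus[2] - 17.3) / 17.3, 0.15)
  expect_equal(sum(f$weights), 1)
  expect_true(all(diff(f$taus) > 0))
})

test_that("degenerate and undersized tc inputs are rejected", {
  expect_error(fitTcDistribution(rexp(20, 1)), "at least 50")
  expect_error(fitTcDistribution(rep(5, 100)), "degenerate")
})

test_that("model selection keeps mono on >= 95% of mono-generated cohorts", {
  set.seed(28)
  picks <- vapply(seq_len(200), function(i)
    fitTcDistribution(rexp(1000, 1 / 5.2))$n_components, integer(1))
  expect_gte(mean(picks == 1L), 0.95)
})

test_that("per-state kinetics comparison reports ratios and rank tests", {
  set.seed(29)
  evA <- data.frame(tc_trans_ms = rexp(150, 1 / 5.2),
                    conductance_pS = rnorm(150, 217, 20))
  expect_equal(compareTcByState(evA, evA)$tc_ratio, 1)
  expect_gt(compareTcByState(evA, evA)$p_value, 0.9)

  evB <- evA; evB$tc_trans_ms <- 2 * evB$tc_trans_ms
  cmp <- compareTcByState(evA, evB)
  expect_equal(cmp$tc_ratio[cmp$state_class == "main"], 2)

  # sparse classes: summary only, no test
  evC <- data.frame(tc_trans_ms = rexp(3, 1), conductance_pS = rep(80, 3))
  out <- compareTcByState(evC, evC)
  expect_true(is.na(out$p_value[out$state_class == "substate"]))
})

test_that("the substate slowdown is detectable at paper-scale event counts", {
  # control substate kinetics vs a doubled-tc condition, n = 129 vs 193
  set.seed(33)
  a <- data.frame(tc_trans_ms = rexp(129, 1 / 8.7),
                  conductance_pS = rnorm(129, 80, 10))
  b <- data.frame(tc_trans_ms = rexp(193, 1 / 17.3),
                  conductance_pS = rnorm(193, 80, 10))
  cmp <- compareTcByState(a, b)
  expect_lte(cmp$p_value[cmp$state_class == "substate"], 1e-4)
})
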