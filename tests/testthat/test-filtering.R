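test_that("median filter leaves constant traces untouched and validates input", {
  tr <- channelTrace(rep(3.2, 500), samplingRate = 100)
  expect_identical(current(medianFilter(tr, 0.5)), rep(3.2, 500))
  expect_error(medianFilter(tr, 10), "longer than trace")
  expect_error(medianFilter(tr, -1), "positive")
})

test_that("median filter preserves step amplitudes of long segments", {
  x <- c(rep(0, 3000), rep(15.19, 3000))
  tr <- channelTrace(x, samplingRate = 4000)
  out <- current(medianFilter(tr, 0.3))
  # identical away from the edge, amplitude exactly preserved
  expect_identical(out[1:2300], x[1:2300])
  expect_identical(out[3700:6000], x[3700:6000])
  expect_equal(max(out) - min(out), 15.19)
})

test_that("median filter matches the direct-definition oracle, odd and even windows", {
  set.seed(5)
  x <- rnorm(400) + rep(c(0, 4), each = 200)
  tr <- channelTrace(x, samplingRate = 100)
  for (w in c(7, 8, 25, 40)) {
    expect_equal(current(medianFilter(tr, w / 100)), naiveRunMedian(x, w),
                 tolerance = 1e-12, info = paste("window", w))
  }
})

test_that("narrow impulses are removed by the median filter", {
  x <- rep(1, 300); x[150:153] <- 9   # impulse width << half window
  tr <- channelTrace(x, samplingRate = 100)
  out <- current(medianFilter(tr, 0.3))
  expect_equal(out, naiveRunMedian(x, 30), tolerance = 1e-12)
  expect_lt(max(out), 2)
})

test_that("median filter is idempotent on resolvable piecewise-constant signals", {
  # odd window: even windows place a midpoint sample at each edge, which a
  # second pass would move
  x <- rep(c(0, 10, 4), times = c(300, 400, 300))
  tr <- channelTrace(x, samplingRate = 100)
  once <- medianFilter(tr, 0.41)
  twice <- medianFilter(once, 0.41)
  expect_identical(current(once), current(twice))
})

test_that("filters preserve length and sampling metadata", {
  tr <- channelTrace(rnorm(512), samplingRate = 256, vm = -50,
                     metadata = list(cond = "x"))
  for (out in list(medianFilter(tr, 0.1), tvdDenoise(tr, 5))) {
    expect_length(current(out), 512)
    expect_identical(samplingRate(out), 256)
    expect_identical(vm(out), -50)
    expect_identical(out@metadata, tr@metadata)
  }
})

test_that("TVD with lambda = 0 is the identity", {
  set.seed(1)
  y <- rnorm(300)
  tr <- channelTrace(y)
  expect_identical(current(tvdDenoise(tr, 0)), y)
})

test_that("TVD converges to the global mean as lambda grows large", {
  set.seed(2)
  y <- rnorm(150) + rep(c(0, 6), each = 75)
  tr <- channelTrace(y, samplingRate = 100)
  out <- current(tvdDenoise(tr, 1e6, iterations = 1e6, tol = 1e-13))
  expect_lt(max(abs(out - mean(y))), 1e-4)
})

test_that("TVD output total variation never exceeds the input's and is
           non-increasing in lambda", {
  set.seed(3)
  y <- rnorm(600) + rep(c(0, 5, 2), each = 200)
  tr <- channelTrace(y, samplingRate = 200)
  tvIn <- sum(abs(diff(y)))
  tvs <- vapply(c(0, 0.5, 2, 10, 100, 1e4), function(lam)
    sum(abs(diff(current(tvdDenoise(tr, lam))))), numeric(1))
  expect_true(all(tvs <= tvIn + 1e-9))
  expect_true(all(diff(tvs) <= 1e-9))
})

test_that("taut-string solutions satisfy the exact dual optimality certificate", {
  set.seed(4)
  for (n in c(2, 5, 60, 200)) for (lam in c(0.02, 0.5, 3, 25)) {
    y <- rnorm(n) + c(rep(0, floor(n / 2)), rep(3, ceiling(n / 2)))
    x <- tvTautString(y, lam)
    expect_true(tvKKTholds(y, lam, x),
                info = sprintf("n=%d lambda=%g", n, lam))
  }
})

test_that("taut string agrees with an independent box-constrained dual QP", {
  set.seed(6)
  for (rep in 1:5) {
    y <- rnorm(40) + rep(c(0, 4), each = 20)
    lam <- runif(1, 0.05, 5)
    expect_equal(tvTautString(y, lam), tvDualQP(y, lam), tolerance = 1e-5)
  }
})

test_that("iterative-clipping TVD converges to the taut-string solution", {
  set.seed(7)
  y <- rnorm(200) + rep(c(0, 4, 1, 6), each = 50)
  tr <- channelTrace(y, samplingRate = 100)
  for (lam in c(0.1, 1, 10, 100)) {
    xm <- current(tvdDenoise(tr, lam, iterations = 5e5, tol = 1e-12))
    expect_lt(max(abs(xm - tvTautString(y, lam))), 1e-6,
              label = sprintf("max deviation at lambda=%g", lam))
  }
})
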