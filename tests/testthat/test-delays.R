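test_that("lagged cross-covariance equals the brute-force double loop", {
  set.seed(40)
  for (i in 1:50) {
    T <- sample(12:50, 1)
    L <- sample(1:floor((T - 1) / 2), 1)
    z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    xi <- z(rnorm(T)); xj <- z(rnorm(T))
    cc <- laggedCrossCov(xi, xj, L)
    expect_equal(cc$lags, -L:L)
    expect_equal(cc$values, oracleLaggedCov(xi, xj, L), tolerance = 1e-12)
    # reversal identity makes exchange of arguments a lag reversal
    expect_equal(laggedCrossCov(xj, xi, L)$values, rev(cc$values),
                 tolerance = 1e-12)
  }
})

test_that("zero-lag autocovariance of a z-scored signal is exactly 1", {
  set.seed(41)
  x <- seriesData(makeSeries(cbind(A = rnorm(60))))[, 1]
  cc <- laggedCrossCov(x, x, 5)
  expect_equal(cc$values[cc$lags == 0], 1, tolerance = 1e-12)
  expect_error(laggedCrossCov(x, x, 30), "maxLag")
})

test_that("a shifted copy puts the covariance extremum at minus the shift", {
  set.seed(42)
  base <- cumsum(rnorm(80))
  z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  xi <- z(base[3:70])            # x_j(t) = x_i(t - 2)
  xj <- z(base[1:68])
  cc <- laggedCrossCov(xi, xj, 6)
  expect_equal(cc$lags[which.max(abs(cc$values))], -2)
})

test_that("parabolic vertex follows the closed form with clamping", {
  expect_equal(parabolicVertex(0.5, 1, 0.5), 0)
  expect_equal(parabolicVertex(0, 1, 0.8), 1 / 3, tolerance = 1e-12)
  expect_equal(parabolicVertex(1, 1, 1), 0)       # degenerate denominator
  expect_equal(parabolicVertex(0, 0.1, 0.199), 1) # clamped to the sample gap
  # exact quadratic: vertex recovered wherever it lies in [-1, 1]
  for (v in c(-0.75, -0.2, 0.4)) {
    y <- function(t) -(t - v)^2
    expect_equal(parabolicVertex(y(-1), y(0), y(1)), v, tolerance = 1e-12)
  }
})

test_that("pearsonDelay is zero on identity, +-shift on shifted copies, antisymmetric", {
  set.seed(43)
  z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- z(bumpSignal(100, peaks = c(15, 40, 62, 88)) + rnorm(100, sd = 0.05))
  expect_equal(pearsonDelay(x, x, 8), 0)
  base <- bumpSignal(124, peaks = c(18, 43, 65, 91)) + rnorm(124, sd = 0.05)
  xi <- z(base[5:100]); xj <- z(base[3:98])   # x_j(t) = x_i(t - 2)
  tij <- pearsonDelay(xi, xj, 8)
  expect_equal(tij, -2, tolerance = 0.35)
  expect_equal(pearsonDelay(xj, xi, 8), -tij, tolerance = 1e-12)
})

test_that("target-peak search picks the closest peak with the documented tie rules", {
  x <- bumpSignal(40, peaks = 22)
  r <- findTargetPeak(x, tSource = 20)
  expect_equal(r$peak, 22L)
  expect_equal(r$edge, "none")

  # two equidistant peaks resolve to the earlier one
  x2 <- bumpSignal(40, peaks = c(17, 23))
  expect_equal(findTargetPeak(x2, 20)$peak, 17L)

  # monotone segment: no interior peak, maximum on the right edge
  mono <- findTargetPeak(seq(0, 5, length.out = 60), 30)
  expect_equal(mono$edge, "right")
  expect_equal(mono$peak, 38L)

  # plateau peaks take the leftmost sample
  xp <- c(rep(0, 10), 1, 2, 2, 2, 1, rep(0, 10))
  expect_equal(findTargetPeak(xp, 12)$peak, 12L)

  # negative polarity finds troughs
  expect_equal(findTargetPeak(-x, 20, polarity = "negative")$peak, 22L)

  expect_error(findTargetPeak(x, 100, windowMin = 1, windowMax = 5),
               "window")
})

test_that("event delays vanish on a region against itself with clean events", {
  x <- bumpSignal(200, peaks = c(20, 60, 100, 140, 180))
  s <- roiTimeSeries(cbind(A = x, B = x), tr = 2.3)
  s@zscored <- TRUE
  ed <- eventDelay(s, "A", "B")
  expect_equal(ed$perEvent, rep(0, ed$nEvents))
  expect_equal(ed$averageEventDelay, 0)
})

test_that("an integer shift between clean signals is recovered within 0.25 TR", {
  x <- bumpSignal(200, peaks = c(20, 60, 100, 140))
  y <- bumpSignal(200, peaks = c(20, 60, 100, 140) + 2)
  s <- roiTimeSeries(cbind(A = x, B = y), tr = 2.3)
  s@zscored <- TRUE
  ed <- eventDelay(s, "A", "B")
  expect_equal(ed$nEvents, 4L)
  expect_true(all(abs(ed$perEvent - 2) < 0.25))
  expect_lt(abs(ed$averageEventDelay - 2), 0.25)
})

test_that("edge-flagged targets are clamped to exactly +-6", {
  # monotone rising target: the window maximum sits on the right edge
  x <- bumpSignal(80, peaks = c(20, 50))
  y <- seq(-1, 4, length.out = 80)
  s <- roiTimeSeries(cbind(A = x, B = y), tr = 2.3)
  s@zscored <- TRUE
  ed <- eventDelay(s, "A", "B")
  expect_true(all(ed$perEvent == 6))
  expect_equal(ed$nClamped, 2L)
})

test_that("imposed lags are recovered from coupled noisy fixtures", {
  set.seed(44)
  for (lag in c(-2, 1.5)) {
    hits <- replicate(40, {
      sim <- genCoupled(recoverySpec(lag = lag))
      abs(eventDelay(sim$series, "R1", "R2")$mean - lag) <= 0.5
    })
    expect_gte(mean(hits), 0.9)
  }
})

test_that("delay matrices have the promised symmetry structure", {
  set.seed(45)
  sim <- genCoupled(simulationSpec(nRegions = 4, nTimepoints = 300,
                                   eventRate = 8, noiseScale = 0.4))
  dp <- delayMatrix(sim$series, "pearson_lag", maxLag = 8)
  expect_identical(values(dp) + t(values(dp)),
                   matrix(0, 4, 4, dimnames = dimnames(values(dp))))
  expect_true(all(abs(values(dp)) <= 8))

  # identical columns give an all-zero event-delay matrix
  x <- bumpSignal(200, peaks = c(20, 70, 120, 170))
  s <- roiTimeSeries(cbind(A = x, B = x, C = x), tr = 2.3)
  s@zscored <- TRUE
  de <- delayMatrix(s, "event_lag", keepPerEvent = TRUE)
  expect_true(all(values(de) == 0))
  expect_true(all(unlist(de@perEvent) == 0))
})
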