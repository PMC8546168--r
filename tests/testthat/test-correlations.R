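test_that("every estimator matches a brute-force Pearson oracle exactly", {
  set.seed(20)
  for (i in 1:50) {
    K <- sample(1:6, 1)
    W <- sample(5:9, 1)
    segS <- matrix(rnorm(K * W), K, W)
    segT <- matrix(rnorm(K * W), K, W)
    st <- makeStacks(segS, segT, pre = 2L)

    for (k in seq_len(K))
      expect_equal(eventCorrelationSingle(st$src, st$tgt, k),
                   oraclePearson(segS[k, ], segT[k, ]), tolerance = 1e-12)
    expect_equal(eventCorrelationMean(st$src, st$tgt)$r,
                 mean(vapply(seq_len(K), function(k)
                   oraclePearson(segS[k, ], segT[k, ]), numeric(1))),
                 tolerance = 1e-12)
    expect_equal(eventCorrelationConcat(st$src, st$tgt),
                 oraclePearson(as.vector(t(segS)), as.vector(t(segT))),
                 tolerance = 1e-12)
    expect_equal(eventCorrelationAverage(st$src, st$tgt),
                 oraclePearson(colMeans(segS), colMeans(segT)),
                 tolerance = 1e-12)

    ts <- rnorm(sample(10:50, 1)); tt <- rnorm(length(ts))
    expect_equal(pearsonFull(ts, tt), oraclePearson(ts, tt),
                 tolerance = 1e-12)
  }
})

test_that("estimators respect correlation identities and affine invariance", {
  set.seed(21)
  seg <- matrix(rnorm(4 * 7), 4, 7)
  st <- makeStacks(seg, seg, pre = 2L)
  expect_equal(eventCorrelationAverage(st$src, st$tgt), 1)
  expect_equal(eventCorrelationConcat(st$src, st$tgt), 1)
  neg <- makeStacks(seg, -seg, pre = 2L)
  expect_equal(eventCorrelationSingle(neg$src, neg$tgt, 2), -1)

  # K = 1 concatenation reduces to the single-event estimator
  one <- makeStacks(seg[1, , drop = FALSE], 2 * seg[1, , drop = FALSE] + 5,
                    pre = 2L)
  expect_equal(eventCorrelationConcat(one$src, one$tgt),
               eventCorrelationSingle(one$src, one$tgt, 1))
  expect_equal(eventCorrelationSingle(one$src, one$tgt, 1), 1)  # affine

  aff <- makeStacks(seg, 3 * seg + 2, pre = 2L)
  expect_equal(eventCorrelationAverage(aff$src, aff$tgt), 1, tolerance = 1e-12)

  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearsonFull(2 * x + 1, y), pearsonFull(x, y),
               tolerance = 1e-12)
  expect_error(pearsonFull(rep(1, 10), rnorm(10)), "constant")
})

test_that("constant segments are excluded from the mean with a count", {
  seg <- rbind(c(1, 2, 3, 2, 1), c(2, 2, 2, 2, 2), c(0, 1, 2, 1, 0))
  tgt <- rbind(c(1, 2, 3, 2, 1), c(0, 1, 0, 1, 0), c(0, 1, 2, 1, 0))
  st <- makeStacks(seg, tgt, pre = 2L)
  res <- eventCorrelationMean(st$src, st$tgt)
  expect_equal(res$nUndefined, 1L)
  expect_equal(res$nUsed, 2L)
  expect_equal(res$r, 1)
})

test_that("fisherZ matches atanh and stays finite at |r| = 1", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_equal(round(fisherZ(0.5), 4), 0.5493)
  expect_true(is.finite(fisherZ(1)) && fisherZ(1) > 5)
  expect_true(is.finite(fisherZ(-1)) && fisherZ(-1) < -5)
})

test_that("pearson_full matrices are exactly symmetric with unit diagonal", {
  set.seed(22)
  s <- makeSeries(matrix(rnorm(150 * 5), 150, 5))
  fc <- fcMatrix(s, "pearson_full")
  v <- values(fc)
  expect_identical(v, t(v))
  expect_equal(unname(diag(v)), rep(1, 5))
  expect_true(all(abs(v) <= 1))
})

test_that("duplicated regions correlate at 1 under every estimator", {
  set.seed(23)
  sim <- genCoupled(simulationSpec(nRegions = 1, nTimepoints = 300,
                                   eventRate = 8, noiseScale = 0.3))
  x <- seriesData(sim$series)[, 1]
  s <- makeSeries(cbind(A = x, B = x))
  for (m in c("pearson_full", "event_single", "event_mean", "event_concat",
              "event_average")) {
    fc <- fcMatrix(s, m)
    expect_equal(values(fc)["A", "B"], 1, tolerance = 1e-9)
  }
})

test_that("event FC diagonal is 1 and event counts are recorded", {
  set.seed(24)
  sim <- genCoupled(simulationSpec(nRegions = 3, nTimepoints = 400,
                                   eventRate = 8, noiseScale = 0.4))
  fc <- fcMatrix(sim$series, "event_average")
  expect_equal(unname(diag(values(fc))), rep(1, 3))
  expect_equal(unname(fc@eventCounts),
               vapply(regionLabels(sim$series), function(l)
                 length(eventTimes(detectEvents(sim$series, l))),
                 integer(1), USE.NAMES = FALSE))
  expect_true(all(values(fc) >= -1 & values(fc) <= 1, na.rm = TRUE))
})

test_that("coupled channels show stronger event correlation than independent ones", {
  set.seed(25)
  wins <- replicate(100, {
    sp <- simulationSpec(nRegions = 3, nTimepoints = 400,
                         noiseModel = "spectral", alpha = 5,
                         noiseScale = 0.25, eventRate = c(10, 0, 10),
                         couplings = data.frame(driver = 1, receiver = 2,
                                                lag = 0, share = 1,
                                                amplitude = 3))
    sim <- genCoupled(sp)
    r <- seedMap(sim$series, "R1", c("R2", "R3"), "event_average")
    r["R2"] > r["R3"]
  })
  expect_gte(mean(wins), 0.95)
})

test_that("event correlations spread wider than full-series Pearson under the null", {
  set.seed(26)
  rP <- rE <- numeric(60)
  for (i in 1:60) {
    sim <- genCoupled(simulationSpec(nRegions = 2, nTimepoints = 200,
                                     eventRate = 8, noiseScale = 1))
    rP[i] <- values(fcMatrix(sim$series, "pearson_full"))[1, 2]
    rE[i] <- values(suppressWarnings(
      fcMatrix(sim$series, "event_average")))[1, 2]
  }
  expect_gt(sd(rE, na.rm = TRUE), sd(rP, na.rm = TRUE))
})
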