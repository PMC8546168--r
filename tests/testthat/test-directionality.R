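.fc2 <- function(m, method = "event_average") {
  labs <- paste0("R", seq_len(nrow(m)))
  dimnames(m) <- list(labs, labs)
  new("FcMatrix", values = m, method = method, params = list(),
      eventCounts = integer(0), nUndefined = as.integer(sum(is.na(m))))
}

test_that("asymmetry is the matrix minus its transpose, with zero total", {
  a <- asymmetry(.fc2(rbind(c(1, 0.8), c(0.5, 1))))
  expect_equal(a@pairwise[1, 2], 0.3)
  expect_equal(a@pairwise[2, 1], -0.3)
  expect_equal(unname(a@perRegion), c(0.3, -0.3))
  expect_identical(a@pairwise, -t(a@pairwise))
  expect_equal(a@global, 0)

  sym <- asymmetry(.fc2(rbind(c(1, 0.4), c(0.4, 1))))
  expect_true(all(sym@pairwise == 0))

  set.seed(30)
  m <- matrix(runif(36, -1, 1), 6); diag(m) <- 1
  full <- asymmetry(.fc2(m))
  expect_identical(full@pairwise, -t(full@pairwise))
  expect_equal(full@global, 0)
  expect_equal(sum(full@perRegion), 0)
})

test_that("missing entries are excluded pairwise and counted", {
  m <- rbind(c(1, 0.8, NA), c(0.2, 1, 0.1), c(0.6, 0.3, 1))
  a <- asymmetry(.fc2(m))
  expect_equal(a@nExcluded, 2L)       # (1,3) and (3,1)
  expect_equal(a@pairwise[1, 2], 0.6)
  expect_equal(unname(a@perRegion), c(0.6, -0.6 + -0.2, 0.2))
})

test_that("shared-event ratios reproduce constructed trigger counts", {
  T <- 120L
  # six events in A; exactly 2 coincide with above-threshold samples of B
  peaksA <- c(10, 25, 40, 60, 80, 100)
  # five events in B; exactly 2 coincide with above-threshold samples of A
  peaksB <- c(10, 25, 50, 70, 90)
  s <- roiTimeSeries(cbind(A = bumpSignal(T, peaksA),
                           B = bumpSignal(T, peaksB)), tr = 2.3)
  s@zscored <- TRUE
  rab <- sharedEventRatio(s, "A", "B")
  expect_equal(rab$nEvents, 6L)
  expect_equal(rab$nShared, 2L)
  expect_equal(rab$ratio, 1 / 3)
  rba <- sharedEventRatio(s, "B", "A")
  expect_equal(rba$nEvents, 5L)
  expect_equal(rba$ratio, 0.4)

  # a region shares every event with itself; never with a silent region
  sSelf <- roiTimeSeries(cbind(A = bumpSignal(T, peaksA),
                               B = bumpSignal(T, peaksA),
                               C = rep(0, T)), tr = 2.3)
  sSelf@zscored <- TRUE
  expect_equal(sharedEventRatio(sSelf, "A", "B")$ratio, 1)
  expect_equal(sharedEventRatio(sSelf, "A", "C")$ratio, 0)
})

test_that("raising the threshold never raises the shared count of a fixed event set", {
  set.seed(31)
  for (i in 1:10) {
    sim <- genCoupled(simulationSpec(nRegions = 2, nTimepoints = 300,
                                     eventRate = 8, noiseScale = 0.5))
    ev <- detectEvents(sim$series, "R1", threshold = 1)
    if (length(eventTimes(ev)) == 0) next
    n <- vapply(c(1, 1.5, 2), function(th)
      sharedEventRatio(sim$series, "R1", "R2", threshold = th,
                       events = ev)$nShared, integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("directionality share ordering is recovered from coupled fixtures", {
  set.seed(32)
  wins <- replicate(100, {
    sim <- genCoupled(recoverySpec(lag = 0, share = 1, shareBack = 0.4,
                                   nTimepoints = 700L,
                                   eventRate = c(16, 16)))
    ab <- sharedEventRatio(sim$series, "R1", "R2", tolerance = 1)$ratio
    ba <- sharedEventRatio(sim$series, "R2", "R1", tolerance = 1)$ratio
    ab > ba
  })
  expect_gte(mean(wins), 0.95)
})

test_that("graph summaries match hand-enumerated small graphs", {
  # complete graph on 4 nodes: clustering 1, path length 1
  m <- matrix(0.9, 4, 4); diag(m) <- 1
  g <- graphSummary(.fc2(m), 0.5)
  expect_equal(g$clusteringCoefficient, 1)
  expect_equal(g$avgPathLength, 1)
  expect_equal(g$nEdges, 6L)

  # 4-node path graph: clustering 0, mean distance (3*1 + 2*2 + 3)/6 = 5/3
  p <- matrix(0, 4, 4); diag(p) <- 1
  p[1, 2] <- p[2, 1] <- p[2, 3] <- p[3, 2] <- p[3, 4] <- p[4, 3] <- 0.9
  gp <- graphSummary(.fc2(p), 0.5)
  expect_equal(gp$clusteringCoefficient, 0)
  expect_equal(gp$avgPathLength, 5 / 3)

  # threshold above every |r|: empty graph reported as undefined
  ge <- graphSummary(.fc2(p), 0.95)
  expect_true(is.na(ge$avgPathLength) && is.na(ge$clusteringCoefficient))
  expect_equal(ge$nEdges, 0L)

  # disconnected pairs are excluded from the average and counted
  d <- matrix(0, 4, 4); diag(d) <- 1
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0.9
  gd <- graphSummary(.fc2(d), 0.5)
  expect_equal(gd$avgPathLength, 1)
  expect_equal(gd$nDisconnectedPairs, 4L)
})
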