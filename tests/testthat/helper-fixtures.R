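# In-code fixtures shared across the suite.

# Wrap a plain matrix as a (optionally z-scored) series.
makeSeries <- function(m, tr = 2.3, zscore = TRUE) {
  s <- roiTimeSeries(m, tr = tr)
  if (zscore) zscoreSeries(s) else s
}

# Deterministic signal with clean unimodal bumps at the given sample
# positions (triangular, width 2*halfWidth+1, peak height `amp`), on a tiny
# negative-offset baseline so the bumps are the only threshold crossings and
# the only local maxima.
bumpSignal <- function(T, peaks, amp = 3, halfWidth = 2, baseline = -0.2) {
  x <- rep(baseline, T)
  for (p in peaks) for (d in -halfWidth:halfWidth) {
    i <- p + d
    if (i >= 1 && i <= T)
      x[i] <- max(x[i], baseline + (amp - baseline) * (1 - abs(d) / (halfWidth + 1)))
  }
  x
}

# Naive textbook Pearson correlation, kept deliberately independent of
# stats::cor and of the package internals: explicit sums.
oraclePearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Brute-force lagged cross-covariance: literal double loop over the defining
# sum for tau >= 0 and the reversal identity for tau < 0.
oracleLaggedCov <- function(xi, xj, L) {
  T <- length(xi)
  one <- function(a, b, tau) {
    s <- 0
    for (t in 1:(T - tau)) s <- s + a[t + tau] * b[t]
    s / T
  }
  vapply(-L:L, function(tau)
    if (tau >= 0) one(xi, xj, tau) else one(xj, xi, -tau), numeric(1))
}

# Event stacks with given segment matrices, for estimator oracle tests.
makeStacks <- function(segS, segT, pre = 2L, post = NULL, threshold = 0.1) {
  W <- ncol(segS)
  if (is.null(post)) post <- W - pre - 1L
  times <- as.integer(seq(pre + 1L, by = W, length.out = nrow(segS)))
  src <- new("EventStack", segments = segS, kind = "target",
             sourceRegion = "a", targetRegion = "a",
             times = times, threshold = threshold,
             pre = as.integer(pre), post = as.integer(post))
  tgt <- new("EventStack", segments = segT, kind = "target",
             sourceRegion = "a", targetRegion = "b",
             times = times, threshold = threshold,
             pre = as.integer(pre), post = as.integer(post))
  list(src = src, tgt = tgt)
}

# Study conditions for the coupled-fixture recovery experiments (chosen as
# hemodynamically smooth, mildly noisy scans; see the methods vignette).
recoverySpec <- function(lag, share = 1, nTimepoints = 400L,
                         eventRate = c(13, 0), shareBack = NULL) {
  couplings <- if (is.null(shareBack)) {
    data.frame(driver = 1, receiver = 2, lag = lag, share = share,
               amplitude = 3)
  } else {
    data.frame(driver = c(1, 2), receiver = c(2, 1), lag = lag,
               share = c(share, shareBack), amplitude = 3)
  }
  simulationSpec(nRegions = 2, nTimepoints = nTimepoints, tr = 2.3,
                 noiseModel = "spectral", alpha = 5, noiseScale = 0.25,
                 eventRate = eventRate, eventAmplitude = 3,
                 couplings = couplings)
}
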