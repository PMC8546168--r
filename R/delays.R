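#' Lagged cross-covariance of two z-scored signals
#'
#' Computes C(tau) = (1/T) * sum_t x_i(t + tau) * x_j(t) for integer lags
#' tau = -L..L, summing over the overlapping sample range and always
#' dividing by the full length T (so C is shrunk toward zero at large lags
#' rather than renormalised).  Negative lags are defined through the
#' reversal identity C_ij(-tau) = C_ji(tau), which makes the delay matrix
#' built from these curves exactly antisymmetric.  For a z-scored signal
#' (population SD) the zero-lag autocovariance C_ii(0) is exactly 1.
#'
#' @param xi,xj numeric vectors of equal length T, z-scored.
#' @param maxLag largest lag L in TRs; must satisfy L < T/2.
#' @return list with \code{lags} (integers -L..L) and \code{values}.
#' @export
laggedCrossCov <- function(xi, xj, maxLag) {
  T <- length(xi)
  stopifnot(length(xj) == T, maxLag >= 0)
  L <- as.integer(maxLag)
  if (L >= T / 2) stop("maxLag must be < T/2 (got L = ", L, ", T = ", T, ")")
  onesided <- function(a, b) vapply(0:L, function(tau)
    sum(a[(1 + tau):T] * b[1:(T - tau)]) / T, numeric(1))
  pos <- onesided(xi, xj)              # tau = 0..L
  neg <- onesided(xj, xi)              # C_ij(-tau) := C_ji(tau)
  list(lags = (-L):L, values = c(rev(neg[-1L]), pos))
}

#' Sub-sample offset of an extremum by parabolic interpolation
#'
#' Fits a parabola through three equally spaced ordinates around a discrete
#' extremum and returns the abscissa of its vertex relative to the centre
#' point: delta = 0.5 * (yMinus - yPlus) / (yMinus - 2*y0 + yPlus).  A
#' near-degenerate denominator (|.| < 1e-12, i.e. three collinear points)
#' returns 0, and the offset is clamped to [-1, 1] so the refined extremum
#' stays between the neighbouring samples.  Works for maxima and minima
#' alike.
#'
#' @param yMinus,y0,yPlus ordinates at the sample before, at, and after the
#'   discrete extremum.
#' @return offset in sample units, in [-1, 1].
#' @examples
#' parabolicVertex(0, 1, 0.8)  # 1/3
#' @export
parabolicVertex <- function(yMinus, y0, yPlus) {
  stopifnot(is.finite(yMinus), is.finite(y0), is.finite(yPlus))
  den <- yMinus - 2 * y0 + yPlus
  if (abs(den) < 1e-12) return(0)
  min(1, max(-1, 0.5 * (yMinus - yPlus) / den))
}

#' Cross-covariance delay between two signals
#'
#' The integer lag at which |C(tau)| is largest, refined by parabolic
#' interpolation of C around that extremum (unrefined if the extremum sits
#' at +-maxLag).  Using the extremum of |C| captures anticorrelated
#' propagation; set \code{positiveOnly = TRUE} to use the maximum of C
#' instead.  Positive tau(i, j) means region i's activity is shifted later
#' than region j's under the C(tau) = (1/T) sum_t x_i(t+tau) x_j(t)
#' indexing; exchanging the arguments flips the sign.
#'
#' @inheritParams laggedCrossCov
#' @param positiveOnly if TRUE, locate the maximum of C rather than the
#'   extremum of |C|.
#' @return lag in TR units (real-valued).
#' @export
pearsonDelay <- function(xi, xj, maxLag, positiveOnly = FALSE) {
  cc <- laggedCrossCov(xi, xj, maxLag)
  y <- if (positiveOnly) cc$values else abs(cc$values)
  if (all(y < 1e-15)) {
    warning("all-zero cross-covariance: delay undefined")
    return(NA_real_)
  }
  e <- which.max(y)
  if (e == 1L || e == length(y)) return(as.numeric(cc$lags[e]))
  cc$lags[e] + parabolicVertex(cc$values[e - 1L], cc$values[e],
                               cc$values[e + 1L])
}

# Locate local extrema (strictly greater/less than neighbours; plateaus take
# their leftmost sample) of x restricted to indices lo..hi.
.localPeaks <- function(x, lo, hi, polarity = "positive") {
  if (polarity == "negative") x <- -x
  seg <- x[lo:hi]
  n <- length(seg)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (seg[i] > seg[i - 1L]) {
      j <- i
      while (j < n && seg[j + 1L] == seg[i]) j <- j + 1L  # plateau run
      if (j <= n - 1L && seg[j + 1L] < seg[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks + lo - 1L
}

#' Closest peak of a target signal around a source event
#'
#' Searches the target signal within \code{[tSource + windowMin,
#' tSource + windowMax]} (default [-6, +8] TRs, clipped to the series
#' bounds) for interior local maxima — strictly greater than both
#' neighbours, plateaus taking their leftmost sample — and returns the one
#' closest to the source time, regardless of amplitude or side; equidistant
#' candidates resolve to the earlier peak.  If the window contains no
#' interior local extremum the window's maximum sample is used, and a
#' maximum sitting on the window edge is flagged so the caller can apply
#' the edge rule (clamped lag).  With \code{polarity = "negative"} local
#' minima are searched instead, for activation/de-activation delays.
#'
#' @param x numeric target signal.
#' @param tSource source event time (1-based sample index); the search
#'   window is placed around it.
#' @param windowMin,windowMax search window in TRs relative to
#'   \code{tSource} (defaults -6 and +8).
#' @param polarity \code{"positive"} (peaks) or \code{"negative"} (troughs).
#' @param anchor sample index distances are measured from; defaults to
#'   \code{tSource}.  [eventDelay()] anchors at the source event's peak,
#'   which is centred at time zero when matching peaks.
#' @return list with \code{peak} (sample index) and \code{edge} (\code{"none"},
#'   \code{"left"} or \code{"right"}).
#' @export
findTargetPeak <- function(x, tSource, windowMin = -6L, windowMax = 8L,
                           polarity = c("positive", "negative"),
                           anchor = tSource) {
  polarity <- match.arg(polarity)
  lo <- max(1L, tSource + as.integer(windowMin))
  hi <- min(length(x), tSource + as.integer(windowMax))
  if (lo > hi) stop("search window does not intersect the series")
  peaks <- .localPeaks(x, lo, hi, polarity)
  if (length(peaks)) {
    d <- abs(peaks - anchor)
    cand <- peaks[d == min(d)]
    return(list(peak = min(cand), edge = "none"))     # tie -> earlier peak
  }
  seg <- if (polarity == "negative") -x[lo:hi] else x[lo:hi]
  m <- lo + which.max(seg) - 1L
  edge <- if (m == lo) "left" else if (m == hi) "right" else "none"
  list(peak = m, edge = edge)
}

# Peak position + parabolic offset of x around index p, restricted to lo..hi;
# offset 0 when p sits on the restriction edge.
.refinedPeak <- function(x, p, lo = 1L, hi = length(x)) {
  if (p <= lo || p >= hi) return(as.numeric(p))
  p + parabolicVertex(x[p - 1L], x[p], x[p + 1L])
}

#' Event-based peak-to-peak delays between two regions
#'
#' For each source event of region i, locates the source peak (the maximum
#' sample within the event window, refined by a parabolic fit) and then,
#' with the source peak centred at time zero, the closest peak of region
#' j's signal — searched within \code{[windowMin, windowMax]} TRs of the
#' crossing, also parabolically refined — and returns the
#' per-event delay tau_k = target peak time - source peak time in TR units.
#' A target peak on the search-window edge yields a clamped lag of exactly
#' \code{-clampAt} or \code{+clampAt} (default 6) with no parabolic
#' refinement, since the fit would be unbounded there.  Also reported are
#' the mean delay over events and the delay between the average source and
#' average target event waveforms.
#'
#' @inheritParams sharedEventRatio
#' @param windowMin,windowMax target search window in TRs (defaults -6, +8).
#' @param clampAt absolute lag assigned to edge-flagged targets (default 6).
#' @param pre,post event window in TRs (see [detectEvents()]).
#' @param polarity search target peaks (\code{"positive"}) or troughs
#'   (\code{"negative"}).
#' @return list with \code{perEvent} (vector of tau_k), \code{mean},
#'   \code{averageEventDelay}, \code{nEvents} and \code{nClamped}.
#' @export
eventDelay <- function(series, source, target, threshold = 1,
                       pre = 2L, post = 4L, windowMin = -6L, windowMax = 8L,
                       clampAt = 6, events = NULL,
                       polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(is(series, "RoiTimeSeries"))
  series <- .ensureZscored(series)
  if (is.null(events))
    events <- detectEvents(series, source, threshold, pre, post)
  if (length(events@times) == 0L) {
    warning("no source events in region '", source, "': delay undefined")
    return(list(perEvent = numeric(0), mean = NA_real_,
                averageEventDelay = NA_real_, nEvents = 0L, nClamped = 0L))
  }
  xi <- seriesData(series)[, source]
  if (!target %in% regionLabels(series))
    stop("unknown region label: ", target)
  xj <- seriesData(series)[, target]
  pre <- events@pre; post <- events@post
  tau <- numeric(length(events@times))
  clamped <- 0L
  for (k in seq_along(events@times)) {
    t0 <- events@times[k]
    swLo <- t0 - pre; swHi <- t0 + post
    ps <- swLo + which.max(xi[swLo:swHi]) - 1L
    sPeak <- .refinedPeak(xi, ps, swLo, swHi)
    tp <- findTargetPeak(xj, t0, windowMin, windowMax, polarity,
                         anchor = sPeak)
    if (tp$edge != "none") {
      tau[k] <- if (tp$edge == "left") -clampAt else clampAt
      clamped <- clamped + 1L
    } else {
      tLo <- max(1L, t0 + as.integer(windowMin))
      tHi <- min(length(xj), t0 + as.integer(windowMax))
      tPeak <- .refinedPeak(xj, tp$peak, tLo, tHi)
      tau[k] <- min(max(tPeak - sPeak, windowMin), windowMax)
    }
  }
  # the same peak matching applied to the average event waveforms
  avgS <- averageEvent(extractEvents(series, events))
  avgT <- averageEvent(extractEvents(series, events, target))
  if (polarity == "negative") avgT <- -avgT
  avgDelay <- .refinedPeak(avgT, which.max(avgT)) -
    .refinedPeak(avgS, which.max(avgS))
  list(perEvent = tau, mean = mean(tau), averageEventDelay = avgDelay,
       nEvents = length(tau), nClamped = clamped)
}

#' Pairwise delay matrix
#'
#' Applies [pearsonDelay()] or [eventDelay()] to every region pair.  The
#' cross-covariance method fills the lower triangle with the negated upper
#' triangle, making tau(i, j) = -tau(j, i) exact; the event method computes
#' every ordered pair independently (source-event sets differ between
#' regions, so the matrix is in general non-symmetric).
#'
#' @param series a [RoiTimeSeries-class] with N >= 2 regions.
#' @param method \code{"pearson_lag"} or \code{"event_lag"}.
#' @param maxLag search half-width for the cross-covariance method
#'   (default 10 TRs).
#' @param keepPerEvent store per-event lag vectors (event method only).
#' @inheritParams eventDelay
#' @return a [DelayMatrix-class] with lags in TR units.
#' @export
delayMatrix <- function(series, method = c("event_lag", "pearson_lag"),
                        maxLag = 10L, threshold = 1, pre = 2L, post = 4L,
                        windowMin = -6L, windowMax = 8L, clampAt = 6,
                        keepPerEvent = FALSE,
                        polarity = c("positive", "negative")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  stopifnot(is(series, "RoiTimeSeries"), nRegions(series) >= 2L)
  series <- .ensureZscored(series)
  labs <- regionLabels(series)
  n <- length(labs)
  v <- matrix(0, n, n, dimnames = list(labs, labs))
  perEvent <- list()
  if (method == "pearson_lag") {
    d <- seriesData(series)
    params <- list(maxLag = as.integer(maxLag))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      tau <- pearsonDelay(d[, i], d[, j], maxLag)
      v[i, j] <- tau
      v[j, i] <- -tau
    }
  } else {
    params <- list(threshold = threshold, pre = as.integer(pre),
                   post = as.integer(post),
                   windowMin = as.integer(windowMin),
                   windowMax = as.integer(windowMax), clampAt = clampAt)
    sets <- lapply(labs, function(l)
      detectEvents(series, l, threshold, pre, post))
    for (i in seq_len(n)) {
      if (length(sets[[i]]@times) == 0L) {
        warning("region '", labs[i], "' has no events; its delay row is NA")
        v[i, ] <- NA_real_
        next
      }
      for (j in seq_len(n)) {
        if (j == i) { v[i, j] <- 0; next }
        ed <- eventDelay(series, labs[i], labs[j], threshold, pre, post,
                         windowMin, windowMax, clampAt,
                         events = sets[[i]], polarity = polarity)
        v[i, j] <- ed$mean
        if (keepPerEvent)
          perEvent[[paste0(labs[i], "->", labs[j])]] <- ed$perEvent
      }
    }
  }
  new("DelayMatrix", values = v, method = method, tr = trSeconds(series),
      perEvent = perEvent, params = params)
}
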