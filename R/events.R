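#' Detect upward threshold crossings in a z-scored signal
#'
#' A crossing is the first sample at or above the threshold after the signal
#' was below it: index t (1-based) with \code{x[t-1] < threshold <= x[t]}.
#' The signal must already be in SD units; thresholds of 1-2 SD give
#' near-identical event sets on typical BOLD data, and 1 SD is the default.
#'
#' @param x numeric vector, z-scored signal of one region.
#' @param threshold detection level in SD units (> 0).
#' @return integer vector of crossing indices (possibly empty), all >= 2.
#' @examples
#' detectCrossings(c(0, 0.5, 1.2, 0.8, 1.5), 1)  # 3 and 5
#' @export
detectCrossings <- function(x, threshold = 1) {
  stopifnot(is.numeric(x), length(x) >= 2L, threshold > 0)
  t <- which(x[-1L] >= threshold & x[-length(x)] < threshold) + 1L
  as.integer(t)
}

#' Convert an event window from seconds to TRs
#'
#' Event segments are specified in TR units; this helper converts a window
#' given in seconds (e.g. "4-5 s before, 9-15 s after", the span of the
#' hemodynamic response) using floor rounding, with a minimum of 1 TR after
#' the crossing.
#'
#' @param preSeconds,postSeconds window extent in seconds.
#' @param tr repetition time in seconds.
#' @return list with integer elements \code{pre} and \code{post}.
#' @examples
#' windowFromSeconds(4.6, 9.2, tr = 2.3)  # pre = 2, post = 4
#' @export
windowFromSeconds <- function(preSeconds, postSeconds, tr) {
  stopifnot(tr > 0, preSeconds >= 0, postSeconds > 0)
  list(pre = as.integer(floor(preSeconds / tr)),
       post = max(1L, as.integer(floor(postSeconds / tr))))
}

#' Detect the source events of one region
#'
#' Runs [detectCrossings()] on a region's z-scored signal and keeps the
#' crossings whose full window \code{[t - pre, t + post]} fits inside the
#' scan; boundary crossings are dropped (not padded) so all extracted
#' segments align, and the drop count is retained.  No minimum inter-event
#' separation is enforced: overlapping windows are allowed.
#'
#' @param series a [RoiTimeSeries-class]; z-scored, or standardised on the
#'   fly with a notice.
#' @param region region label.
#' @param threshold SD-unit threshold (default 1).
#' @param pre,post window extent in TRs before/after the crossing
#'   (defaults 2 and 4, i.e. ~4.6 s before and ~9.2 s after at TR 2.3 s).
#' @return an [EventSet-class].
#' @export
detectEvents <- function(series, region, threshold = 1, pre = 2L, post = 4L) {
  stopifnot(is(series, "RoiTimeSeries"))
  series <- .ensureZscored(series)
  if (!region %in% regionLabels(series))
    stop("unknown region label: ", region)
  pre <- as.integer(pre); post <- as.integer(post)
  x <- seriesData(series)[, region]
  t <- detectCrossings(x, threshold)
  keep <- t - pre >= 1L & t + post <= length(x)
  new("EventSet", region = region, times = t[keep], threshold = threshold,
      pre = pre, post = post, nTimepoints = length(x),
      dropped = sum(!keep))
}

#' Extract source or target event segments
#'
#' Cuts one segment \code{[t - pre, t + post]} per event time from the named
#' target region's signal.  When \code{targetRegion} equals the event set's
#' own region the stack is a source stack (rows reach the threshold at the
#' alignment column); otherwise it is a target stack cut at exactly the same
#' times as the source, which is what makes the resulting correlations
#' directional.
#'
#' @param series a [RoiTimeSeries-class] (z-scored, or standardised on the
#'   fly).
#' @param events an [EventSet-class] from [detectEvents()].
#' @param targetRegion region to cut segments from; defaults to the event
#'   set's own region (source stack).
#' @return an [EventStack-class] (K x W matrix, W = pre + post + 1).
#' @export
extractEvents <- function(series, events, targetRegion = events@region) {
  stopifnot(is(series, "RoiTimeSeries"), is(events, "EventSet"))
  series <- .ensureZscored(series)
  if (!targetRegion %in% regionLabels(series))
    stop("unknown region label: ", targetRegion)
  x <- seriesData(series)[, targetRegion]
  W <- events@pre + events@post + 1L
  seg <- matrix(NA_real_, nrow = length(events@times), ncol = W)
  for (k in seq_along(events@times))
    seg[k, ] <- x[(events@times[k] - events@pre):(events@times[k] + events@post)]
  new("EventStack", segments = seg,
      kind = if (targetRegion == events@region) "source" else "target",
      sourceRegion = events@region, targetRegion = targetRegion,
      times = events@times, threshold = events@threshold,
      pre = events@pre, post = events@post)
}

#' Average the segments of an event stack
#'
#' Column-wise arithmetic mean over the K segments, yielding the average
#' source (or target) event waveform of length W.  For source stacks this
#' average is effectively an empirical, region-local estimate of the
#' hemodynamic response.
#'
#' @param stack an [EventStack-class] with K >= 1.
#' @return numeric vector of length \code{pre + post + 1}.
#' @export
averageEvent <- function(stack) {
  stopifnot(is(stack, "EventStack"))
  if (nrow(stack@segments) == 0L)
    stop("no events: cannot average an empty stack (",
         stack@sourceRegion, " -> ", stack@targetRegion, ")")
  colMeans(stack@segments)
}
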