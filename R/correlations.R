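#' @name event-correlations
#' @title Event-based correlation estimators
#'
#' @description
#' Five ways of correlating two regions i (source) and j (target), from the
#' conventional full-series Pearson correlation to estimators restricted to
#' the large-amplitude events of the source:
#' \describe{
#'   \item{\code{pearsonFull}}{Pearson correlation of the whole time series;
#'     symmetric by construction.}
#'   \item{\code{eventCorrelationSingle}}{Pearson correlation of the k-th
#'     source segment with the k-th target segment — the natural choice for
#'     isolated transient events.}
#'   \item{\code{eventCorrelationMean}}{mean of the K per-event correlations.}
#'   \item{\code{eventCorrelationConcat}}{Pearson correlation of the
#'     concatenated source segments with the concatenated target segments.}
#'   \item{\code{eventCorrelationAverage}}{Pearson correlation of the average
#'     source event with the average target event — the default estimator for
#'     whole-scan connectivity.}
#' }
#' Because the source-event sets of two regions differ, every event estimator
#' is in general asymmetric in (i, j): that asymmetry is the directionality
#' signal, not an artifact.  Per-event correlations that are undefined
#' (constant segment) are excluded from the mean with a count rather than
#' propagated.
#'
#' @param sourceStack,targetStack matching [EventStack-class]es (same K and
#'   W), the target cut at the source's event times.
#' @param k event index, 1..K.
#' @return the correlation estimate, or for \code{eventCorrelationMean} a
#'   list with elements \code{r} (mean), \code{nUsed} and \code{nUndefined}.
NULL

.pearson <- function(a, b) {
  if (length(a) < 3L) stop("need at least 3 samples for a correlation")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Full-series Pearson correlation
#' @param xi,xj numeric vectors of equal length >= 3.
#' @rdname event-correlations
#' @export
pearsonFull <- function(xi, xj) {
  stopifnot(length(xi) == length(xj))
  r <- .pearson(xi, xj)
  if (is.na(r)) stop("correlation undefined: constant input series")
  r
}

.checkStacks <- function(sourceStack, targetStack) {
  stopifnot(is(sourceStack, "EventStack"), is(targetStack, "EventStack"))
  if (nrow(sourceStack@segments) != nrow(targetStack@segments) ||
      ncol(sourceStack@segments) != ncol(targetStack@segments))
    stop("source and target stacks must have matching dimensions")
  if (nrow(sourceStack@segments) < 1L) stop("no events in stack")
}

#' @rdname event-correlations
#' @export
eventCorrelationSingle <- function(sourceStack, targetStack, k) {
  .checkStacks(sourceStack, targetStack)
  stopifnot(k >= 1L, k <= nrow(sourceStack@segments))
  .pearson(sourceStack@segments[k, ], targetStack@segments[k, ])
}

#' @rdname event-correlations
#' @export
eventCorrelationMean <- function(sourceStack, targetStack) {
  .checkStacks(sourceStack, targetStack)
  K <- nrow(sourceStack@segments)
  rk <- vapply(seq_len(K), function(k)
    .pearson(sourceStack@segments[k, ], targetStack@segments[k, ]),
    numeric(1))
  nUndef <- sum(is.na(rk))
  if (nUndef == K) {
    warning("all per-event correlations undefined")
    return(list(r = NA_real_, nUsed = 0L, nUndefined = nUndef))
  }
  list(r = mean(rk, na.rm = TRUE), nUsed = K - nUndef, nUndefined = nUndef)
}

#' @rdname event-correlations
#' @export
eventCorrelationConcat <- function(sourceStack, targetStack) {
  .checkStacks(sourceStack, targetStack)
  a <- as.vector(t(sourceStack@segments))  # row-major concatenation
  b <- as.vector(t(targetStack@segments))
  .pearson(a, b)
}

#' @rdname event-correlations
#' @export
eventCorrelationAverage <- function(sourceStack, targetStack) {
  .checkStacks(sourceStack, targetStack)
  .pearson(averageEvent(sourceStack), averageEvent(targetStack))
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh(r)} with |r| clipped to 1 - 1e-7 so that perfect correlations
#' map to a large finite value instead of infinity.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return transformed value(s).
#' @examples
#' fisherZ(0.5)  # 0.5493
#' @export
fisherZ <- function(r) {
  stopifnot(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

.eventEstimator <- function(method) {
  switch(method,
    event_single  = function(s, t, k) eventCorrelationSingle(s, t, k),
    event_mean    = function(s, t, k) eventCorrelationMean(s, t)$r,
    event_concat  = function(s, t, k) eventCorrelationConcat(s, t),
    event_average = function(s, t, k) eventCorrelationAverage(s, t),
    stop("unknown event method: ", method))
}

#' Assemble a functional-connectivity matrix
#'
#' Entry (i, j) is the chosen estimator with region i as source and region j
#' as target.  \code{"pearson_full"} ignores events and yields an exactly
#' symmetric matrix with unit diagonal; the event methods detect each source
#' region's events once and correlate its source stack with the target stack
#' of every other region, so rows of a region with zero usable events are NA
#' (with a warning) and the matrix is in general asymmetric.
#'
#' @param series a [RoiTimeSeries-class] with N >= 2 regions (z-scored, or
#'   standardised on the fly).
#' @param method one of \code{"pearson_full"}, \code{"event_single"},
#'   \code{"event_mean"}, \code{"event_concat"}, \code{"event_average"}
#'   (the whole-scan default among the event estimators).
#' @param threshold,pre,post event parameters (see [detectEvents()]).
#' @param k event index used by \code{"event_single"}.
#' @return an [FcMatrix-class].
#' @examples
#' set.seed(1)
#' s <- zscoreSeries(roiTimeSeries(matrix(rnorm(400), 100, 4), tr = 2.3))
#' fcMatrix(s, "pearson_full")
#' @export
fcMatrix <- function(series, method = c("event_average", "pearson_full",
                                        "event_single", "event_mean",
                                        "event_concat"),
                     threshold = 1, pre = 2L, post = 4L, k = 1L) {
  method <- match.arg(method)
  stopifnot(is(series, "RoiTimeSeries"), nRegions(series) >= 2L)
  series <- .ensureZscored(series)
  labs <- regionLabels(series)
  n <- length(labs)
  v <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  params <- list(threshold = threshold, pre = as.integer(pre),
                 post = as.integer(post))
  if (method == "pearson_full") {
    v <- cor(seriesData(series))
    v <- (v + t(v)) / 2  # enforce exact symmetry against rounding
    diag(v) <- 1
    return(new("FcMatrix", values = v, method = method, params = list(),
               eventCounts = integer(0), nUndefined = 0L))
  }
  est <- .eventEstimator(method)
  counts <- integer(n); names(counts) <- labs
  for (i in seq_len(n)) {
    ev <- detectEvents(series, labs[i], threshold, pre, post)
    counts[i] <- length(ev@times)
    if (counts[i] == 0L || (method == "event_single" && counts[i] < k)) {
      warning("region '", labs[i], "' has ", counts[i],
              " usable events; its source row is undefined")
      next
    }
    src <- extractEvents(series, ev)
    for (j in seq_len(n)) {
      tgt <- if (j == i) src else extractEvents(series, ev, labs[j])
      v[i, j] <- est(src, tgt, k)
    }
  }
  new("FcMatrix", values = v, method = method, params = params,
      eventCounts = counts, nUndefined = sum(is.na(v)))
}

#' One-source-vs-many-targets event correlation map
#'
#' Seed-map mode: detects the events of a single source region and returns
#' the chosen event estimator against every other region (or every voxel
#' column, when the series was extracted from a volumetric grid) without
#' building the full N x N matrix.
#'
#' @inheritParams fcMatrix
#' @param source source region label.
#' @param targets target labels (default: all regions, source included).
#' @return named numeric vector of correlations (NA where undefined).
#' @export
seedMap <- function(series, source, targets = regionLabels(series),
                    method = c("event_average", "event_single",
                               "event_mean", "event_concat"),
                    threshold = 1, pre = 2L, post = 4L, k = 1L) {
  method <- match.arg(method)
  stopifnot(is(series, "RoiTimeSeries"))
  series <- .ensureZscored(series)
  ev <- detectEvents(series, source, threshold, pre, post)
  if (length(ev@times) == 0L) {
    warning("source region '", source, "' has no usable events")
    return(structure(rep(NA_real_, length(targets)), names = targets))
  }
  src <- extractEvents(series, ev)
  est <- .eventEstimator(method)
  vapply(targets, function(lab)
    est(src, extractEvents(series, ev, lab), k), numeric(1))
}
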