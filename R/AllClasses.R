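#' @import methods
#' @importFrom stats cor quantile rnorm rexp runif sd fft mvfft dgamma rpois
#' @importFrom utils read.table write.table head
NULL

#' Regional BOLD time-series container
#'
#' Holds a time-by-region matrix of BOLD (or BOLD-like) signals together with
#' the repetition time (TR) and region labels.  Rows are time points sampled
#' every \code{tr} seconds; columns are regions, labelled by
#' \code{colnames(data)}.  The \code{zscored} flag records whether each column
#' has been standardised to zero mean and unit population SD, which is the
#' representation every event operation expects (thresholds are in SD units).
#'
#' @slot data numeric matrix, T x N, with unique column names.
#' @slot tr repetition time in seconds (> 0).
#' @slot zscored logical; if \code{TRUE} each column has mean ~0 and
#'   population SD ~1 (checked by the validity method to 1e-8).
#'
#' @seealso [roiTimeSeries()], [zscoreSeries()], [readSeriesTable()]
#' @export
setClass("RoiTimeSeries",
  representation(data = "matrix", tr = "numeric", zscored = "logical"),
  prototype(tr = 1, zscored = FALSE)
)

setValidity("RoiTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L) return("T >= 2 required (at least two time points)")
  if (ncol(d) < 1L) return("N >= 1 required (at least one region)")
  if (is.null(colnames(d))) return("region labels (colnames) required")
  if (anyDuplicated(colnames(d))) return("region labels must be unique")
  if (anyNA(d) || any(!is.finite(d)))
    return("missing or non-finite values are not supported")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a single positive number of seconds")
  if (length(object@zscored) != 1L) return("zscored must be a single flag")
  if (isTRUE(object@zscored)) {
    m <- colMeans(d)
    s <- sqrt(colMeans(sweep(d, 2L, m)^2))
    if (any(abs(m) > 1e-8) || any(abs(s - 1) > 1e-8))
      return("zscored is TRUE but columns are not standardised")
  }
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data numeric T x N matrix (rows = time points, columns = regions).
#' @param tr repetition time in seconds.
#' @param labels optional character vector of N region names; defaults to
#'   existing column names, or \code{"R1"..."RN"}.
#' @param zscored logical, whether \code{data} is already standardised.
#' @return A [RoiTimeSeries-class] object.
#' @examples
#' x <- roiTimeSeries(cbind(a = rnorm(50), b = rnorm(50)), tr = 2.3)
#' nTimepoints(x); nRegions(x)
#' @export
roiTimeSeries <- function(data, tr = 1, labels = NULL, zscored = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(labels)) {
    colnames(data) <- labels
  } else if (is.null(colnames(data))) {
    colnames(data) <- paste0("R", seq_len(ncol(data)))
  }
  new("RoiTimeSeries", data = data, tr = tr, zscored = zscored)
}

#' Set of source events (threshold crossings) for one region
#'
#' Records the upward threshold-crossing times of one region's z-scored
#' signal, restricted to crossings whose full extraction window
#' \code{[t - pre, t + post]} fits inside the scan; crossings too close to
#' either end are dropped and counted in \code{dropped}.
#'
#' @slot region region label the events belong to.
#' @slot times strictly increasing integer sample indices (1-based).
#' @slot threshold detection threshold in SD units.
#' @slot pre,post window extent in TRs before/after the crossing.
#' @slot nTimepoints length of the originating series (for window checks).
#' @slot dropped number of crossings discarded at the scan boundaries.
#' @seealso [detectEvents()], [detectCrossings()]
#' @export
setClass("EventSet",
  representation(region = "character", times = "integer",
                 threshold = "numeric", pre = "integer", post = "integer",
                 nTimepoints = "integer", dropped = "integer")
)

setValidity("EventSet", function(object) {
  t <- object@times
  if (length(t) && any(diff(t) <= 0L)) return("times must be strictly increasing")
  if (object@pre < 0L) return("pre must be >= 0")
  if (object@post < 1L) return("post must be >= 1")
  if (length(t) && (t[1L] - object@pre < 1L ||
                    t[length(t)] + object@post > object@nTimepoints))
    return("every retained time must admit the full [t-pre, t+post] window")
  if (object@threshold <= 0) return("threshold must be > 0 SD")
  TRUE
})

#' Stack of extracted event segments
#'
#' A K x W matrix of signal segments, one row per retained event, all aligned
#' on the crossing (column \code{pre + 1}).  \code{kind = "source"} stacks are
#' cut from the region whose crossings defined the events and therefore reach
#' the threshold at the alignment column; \code{kind = "target"} stacks are
#' cut from another region at exactly the same times.
#'
#' @slot segments numeric K x W matrix, W = pre + post + 1 (K = 0 allowed).
#' @slot kind \code{"source"} or \code{"target"}.
#' @slot sourceRegion,targetRegion region labels (equal for source stacks).
#' @slot times crossing times the rows were cut at.
#' @slot threshold,pre,post the event parameters used.
#' @seealso [extractEvents()], [averageEvent()]
#' @export
setClass("EventStack",
  representation(segments = "matrix", kind = "character",
                 sourceRegion = "character", targetRegion = "character",
                 times = "integer", threshold = "numeric",
                 pre = "integer", post = "integer")
)

setValidity("EventStack", function(object) {
  W <- object@pre + object@post + 1L
  if (ncol(object@segments) != W)
    return("segment width must equal pre + post + 1")
  if (nrow(object@segments) != length(object@times))
    return("one row per crossing time required")
  if (!object@kind %in% c("source", "target"))
    return("kind must be 'source' or 'target'")
  if (object@kind == "source" && nrow(object@segments) &&
      any(object@segments[, object@pre + 1L] < object@threshold - 1e-9))
    return("source rows must be at/above threshold at the alignment column")
  TRUE
})

.FC_METHODS <- c("pearson_full", "event_single", "event_mean",
                 "event_concat", "event_average")

#' Functional-connectivity matrix
#'
#' An N x N matrix of correlation values between regions, tagged with the
#' estimator that produced it.  \code{pearson_full} matrices are symmetric
#' with unit diagonal; the event-based estimators are computed with row
#' regions as sources and column regions as targets and are in general
#' asymmetric, which is what the directionality measures exploit.  Entries
#' that could not be estimated (e.g. a region without usable events, or a
#' constant segment) are \code{NA} and counted in \code{nUndefined}.
#'
#' @slot values numeric N x N matrix with region dimnames; entries in
#'   [-1, 1] or NA.
#' @slot method one of \code{"pearson_full"}, \code{"event_single"},
#'   \code{"event_mean"}, \code{"event_concat"}, \code{"event_average"}.
#' @slot params list of the event parameters used (threshold, pre, post, ...).
#' @slot eventCounts integer vector of usable source events per region
#'   (empty for \code{pearson_full}).
#' @slot nUndefined count of NA entries.
#' @seealso [fcMatrix()], [asymmetry()], [graphSummary()]
#' @export
setClass("FcMatrix",
  representation(values = "matrix", method = "character", params = "list",
                 eventCounts = "integer", nUndefined = "integer")
)

setValidity("FcMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must carry identical row/column region labels")
  if (!object@method %in% .FC_METHODS)
    return(paste("method must be one of:", paste(.FC_METHODS, collapse = ", ")))
  ok <- is.na(v) | (v >= -1 - 1e-9 & v <= 1 + 1e-9)
  if (!all(ok)) return("correlation entries must lie in [-1, 1] or be NA")
  TRUE
})

#' Inter-regional delay matrix
#'
#' An N x N matrix of temporal lags in TR units.  With
#' \code{method = "pearson_lag"} the entry (i, j) is the parabolic-refined lag
#' of the extremum of the lagged cross-covariance and the matrix is exactly
#' antisymmetric.  With \code{method = "event_lag"} the entry is the mean
#' event-wise peak-to-peak delay from source region i to target region j,
#' which need not be antisymmetric because the two regions' source-event sets
#' differ.  Positive tau(i, j) means region i's activity is shifted later
#' than region j's under the cross-covariance indexing C(tau) =
#' (1/T) sum_t x_i(t + tau) x_j(t).
#'
#' @slot values numeric N x N lag matrix (TR units), NA where undefined.
#' @slot method \code{"pearson_lag"} or \code{"event_lag"}.
#' @slot tr repetition time in seconds (multiply lags by it for seconds).
#' @slot perEvent optional list of per-event lag vectors keyed
#'   \code{"source->target"} (event method only).
#' @slot params parameters used (maxLag or window/threshold/pre/post).
#' @seealso [delayMatrix()], [pearsonDelay()], [eventDelay()]
#' @export
setClass("DelayMatrix",
  representation(values = "matrix", method = "character", tr = "numeric",
                 perEvent = "list", params = "list")
)

setValidity("DelayMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (!object@method %in% c("pearson_lag", "event_lag"))
    return("method must be 'pearson_lag' or 'event_lag'")
  TRUE
})

#' Correlation-asymmetry decomposition
#'
#' The pairwise difference D(i, j) = r(i, j) - r(j, i) of an event
#' functional-connectivity matrix, its per-region row sums and its global
#' sum.  D is exactly antisymmetric, so the global sum over a complete matrix
#' is zero; the informative quantities are the pairwise entries and the
#' per-region sums, whose signs indicate preferred direction of
#' co-activation.
#'
#' @slot pairwise antisymmetric N x N matrix D.
#' @slot perRegion named vector of row sums over defined pairs.
#' @slot global sum over all defined ordered pairs.
#' @slot nExcluded number of ordered pairs excluded because either
#'   orientation was NA.
#' @seealso [asymmetry()]
#' @export
setClass("AsymmetryResult",
  representation(pairwise = "matrix", perRegion = "numeric",
                 global = "numeric", nExcluded = "integer")
)

#' @describeIn RoiTimeSeries-class number of time points T.
#' @param x,object an object of the documented class.
#' @export
nTimepoints <- function(x) nrow(x@data)

#' @describeIn RoiTimeSeries-class number of regions N.
#' @export
nRegions <- function(x) ncol(x@data)

#' @describeIn RoiTimeSeries-class region labels.
#' @export
regionLabels <- function(x) colnames(x@data)

#' @describeIn RoiTimeSeries-class the T x N signal matrix.
#' @export
seriesData <- function(x) x@data

#' @describeIn RoiTimeSeries-class repetition time in seconds.
#' @export
trSeconds <- function(x) x@tr

#' @describeIn RoiTimeSeries-class whether columns are standardised.
#' @export
isZscored <- function(x) x@zscored

#' @describeIn EventSet-class crossing times of an event set (also works for
#'   an [EventStack-class]).
#' @export
eventTimes <- function(x) x@times

#' Extract the numeric matrix of an FcMatrix, DelayMatrix or EventStack
#' @param x an [FcMatrix-class], [DelayMatrix-class] or [EventStack-class].
#' @return the underlying numeric matrix.
#' @export
values <- function(x) {
  if (is(x, "EventStack")) x@segments else x@values
}

#' @describeIn FcMatrix-class the estimator tag.
#' @export
fcMethod <- function(x) x@method

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d time points x %d regions, TR = %g s%s\n",
              nrow(object@data), ncol(object@data), object@tr,
              if (object@zscored) ", z-scored" else ""))
  lab <- colnames(object@data)
  cat("  regions:", paste(head(lab, 6L), collapse = ", "),
      if (length(lab) > 6L) sprintf("... (%d more)", length(lab) - 6L) else "",
      "\n")
})

setMethod("show", "EventSet", function(object) {
  cat(sprintf(
    "EventSet: region '%s', %d events (theta = %g SD, window -%d/+%d TR, %d dropped)\n",
    object@region, length(object@times), object@threshold,
    object@pre, object@post, object@dropped))
})

setMethod("show", "EventStack", function(object) {
  cat(sprintf("EventStack (%s): %d events x %d samples, %s -> %s\n",
              object@kind, nrow(object@segments), ncol(object@segments),
              object@sourceRegion, object@targetRegion))
})

setMethod("show", "FcMatrix", function(object) {
  cat(sprintf("FcMatrix: %d x %d, method = %s, %d undefined entr%s\n",
              nrow(object@values), ncol(object@values), object@method,
              object@nUndefined, if (object@nUndefined == 1L) "y" else "ies"))
})

setMethod("show", "DelayMatrix", function(object) {
  cat(sprintf("DelayMatrix: %d x %d, method = %s, lags in TR units (TR = %g s)\n",
              nrow(object@values), ncol(object@values), object@method,
              object@tr))
})

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf(
    "AsymmetryResult: %d regions, global sum %.3g, %d pair(s) excluded\n",
    nrow(object@pairwise), object@global, object@nExcluded))
})
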