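#' Correlation asymmetry of an event FC matrix
#'
#' Subtracts the transposed matrix from the matrix itself:
#' D(i, j) = r(i, j) - r(j, i).  D is exactly antisymmetric, so its global
#' sum over a complete matrix is zero by construction; the per-pair entries
#' and the per-region row sums A_i = sum_j D(i, j) carry the directional
#' information (positive A_i: region i correlates more strongly as a source
#' than as a target).  Pairs where either orientation is NA are excluded from
#' all sums and counted.
#'
#' @param fc an [FcMatrix-class]; an event method is expected (a symmetric
#'   Pearson matrix is accepted but yields all zeros).
#' @return an [AsymmetryResult-class].
#' @export
asymmetry <- function(fc) {
  stopifnot(is(fc, "FcMatrix"))
  v <- fc@values
  D <- v - t(v)
  excluded <- is.na(D)
  diag(excluded) <- FALSE
  Dz <- D
  Dz[is.na(Dz)] <- 0
  perRegion <- rowSums(Dz)
  new("AsymmetryResult", pairwise = D, perRegion = perRegion,
      global = sum(perRegion), nExcluded = as.integer(sum(excluded)))
}

#' Shared-event directionality ratio
#'
#' The fraction of region i's source events at whose crossing time region
#' j's signal is also at or above the threshold (i.e. the source event of i
#' is simultaneously a trigger in j).  The ratio is directional: it is
#' normalised by i's event count, so ratio(i, j) != ratio(j, i) in general.
#' An optional tolerance accepts j being above threshold anywhere within
#' \code{tolerance} TRs of the crossing (default 0: the exact sample).
#'
#' @param series a [RoiTimeSeries-class] (z-scored, or standardised on the
#'   fly).
#' @param source,target region labels (i and j).
#' @param threshold SD-unit threshold (default 1).
#' @param events optional precomputed [EventSet-class] for the source;
#'   detected at \code{threshold} if omitted.
#' @param tolerance half-width, in TRs, of the window around the crossing in
#'   which the target may be above threshold (integer >= 0).
#' @return list with \code{ratio} in [0, 1], \code{nShared} and
#'   \code{nEvents}.
#' @export
sharedEventRatio <- function(series, source, target, threshold = 1,
                             events = NULL, tolerance = 0L) {
  stopifnot(is(series, "RoiTimeSeries"), tolerance >= 0L)
  series <- .ensureZscored(series)
  if (is.null(events))
    events <- detectEvents(series, source, threshold)
  stopifnot(is(events, "EventSet"))
  if (!target %in% regionLabels(series))
    stop("unknown region label: ", target)
  if (length(events@times) == 0L) {
    warning("source region '", source, "' has no events; ratio undefined")
    return(list(ratio = NA_real_, nShared = 0L, nEvents = 0L))
  }
  xj <- seriesData(series)[, target]
  tol <- as.integer(tolerance)
  shared <- vapply(events@times, function(t) {
    idx <- max(1L, t - tol):min(length(xj), t + tol)
    any(xj[idx] >= threshold)
  }, logical(1))
  list(ratio = mean(shared), nShared = as.integer(sum(shared)),
       nEvents = length(shared))
}

#' Thresholded-graph summary of an FC matrix
#'
#' Builds a binary undirected graph with an edge wherever the symmetrised
#' absolute correlation reaches \code{edgeThreshold} (symmetrisation:
#' elementwise max of |r(i, j)| and |r(j, i)| over the defined orientations;
#' a pair with both orientations missing forms no edge),
#' then reports the average shortest-path length over connected pairs and
#' the global clustering coefficient (transitivity).
#'
#' @param fc an [FcMatrix-class].
#' @param edgeThreshold absolute-correlation cutoff in (0, 1).
#' @return list with \code{avgPathLength}, \code{clusteringCoefficient},
#'   \code{nEdges}, \code{nDisconnectedPairs} and \code{nMissingEntries};
#'   metrics are NA for an empty graph.
#' @export
graphSummary <- function(fc, edgeThreshold) {
  stopifnot(is(fc, "FcMatrix"),
            edgeThreshold > -1, edgeThreshold < 1)
  v <- abs(fc@values)
  nMissing <- sum(is.na(v))
  s <- pmax(v, t(v), na.rm = TRUE)     # NA only where both orientations NA
  s[is.na(s)] <- -Inf
  diag(s) <- -Inf
  adj <- (s >= edgeThreshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  nEdges <- igraph::ecount(g)
  if (nEdges == 0L) {
    return(list(avgPathLength = NA_real_, clusteringCoefficient = NA_real_,
                nEdges = 0L,
                nDisconnectedPairs = nrow(v) * (nrow(v) - 1L) / 2L,
                nMissingEntries = nMissing))
  }
  dm <- igraph::distances(g)
  ut <- dm[upper.tri(dm)]
  nDisc <- sum(is.infinite(ut))
  apl <- if (all(is.infinite(ut))) NA_real_ else mean(ut[is.finite(ut)])
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) cc <- NA_real_
  list(avgPathLength = apl, clusteringCoefficient = cc,
       nEdges = as.integer(nEdges), nDisconnectedPairs = as.integer(nDisc),
       nMissingEntries = as.integer(nMissing))
}
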