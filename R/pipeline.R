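.distSummary <- function(m) {
  v <- m[row(m) != col(m)]
  v <- v[!is.na(v)]
  if (!length(v))
    return(list(mean = NA, sd = NA, q05 = NA, q25 = NA, median = NA,
                q75 = NA, q95 = NA, n = 0L))
  q <- unname(quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  list(mean = mean(v), sd = sd(v), q05 = q[1], q25 = q[2], median = q[3],
       q75 = q[4], q95 = q[5], n = length(v))
}

.writeMatrixTsv <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Build a validated pipeline configuration
#'
#' Collects every pipeline parameter, validates it up front (before any
#' computation), and round-trips losslessly through JSON via
#' [jsonlite::toJSON()]/[jsonlite::fromJSON()].
#'
#' @param input path to a time-series table (TSV/CSV with a header of region
#'   labels), or \code{NULL} when \code{series} is given directly to
#'   [runPipeline()].
#' @param tr repetition time in seconds.
#' @param threshold event threshold in SD units.
#' @param pre,post event window in TRs.
#' @param fcMethods event FC estimators to compute alongside
#'   \code{pearson_full}.
#' @param maxLag cross-covariance search half-width (TRs).
#' @param windowMin,windowMax,clampAt event-delay search window (TRs).
#' @param edgeThreshold absolute-correlation cutoff for the graph summary.
#' @param seed integer RNG seed recorded with the run.
#' @param outDir output directory (created if needed).
#' @param delimiter input field separator.
#' @return a named list of class \code{"nldfcConfig"}.
#' @export
runConfig <- function(input = NULL, tr = 2.3, threshold = 1, pre = 2L,
                      post = 4L, fcMethods = "event_average", maxLag = 10L,
                      windowMin = -6L, windowMax = 8L, clampAt = 6,
                      edgeThreshold = 0.5, seed = 1L, outDir = ".",
                      delimiter = "\t") {
  cfg <- list(input = input, tr = tr, threshold = threshold,
              pre = as.integer(pre), post = as.integer(post),
              fcMethods = fcMethods, maxLag = as.integer(maxLag),
              windowMin = as.integer(windowMin),
              windowMax = as.integer(windowMax),
              clampAt = as.numeric(clampAt),
              edgeThreshold = edgeThreshold, seed = as.integer(seed),
              outDir = outDir, delimiter = delimiter)
  stopifnot(cfg$tr > 0, cfg$threshold > 0, cfg$pre >= 0L, cfg$post >= 1L,
            cfg$maxLag >= 1L, cfg$windowMin < cfg$windowMax,
            cfg$edgeThreshold > -1, cfg$edgeThreshold < 1,
            all(cfg$fcMethods %in% .FC_METHODS))
  class(cfg) <- "nldfcConfig"
  cfg
}

#' Run the full event-connectivity pipeline
#'
#' Reads (or takes) a regional time-series table, z-scores it, and writes
#' the complete artifact set to \code{config$outDir}: the per-region event
#' catalogs (\code{events.json}), the Pearson and requested event FC
#' matrices (\code{fc_<method>.tsv}), the pairwise correlation asymmetry
#' (\code{asymmetry.tsv}), both delay matrices (\code{delay_pearson.tsv},
#' \code{delay_event.tsv}) and a run report (\code{report.json}) holding the
#' configuration, event/drop/undefined counts, graph summaries and the
#' distribution summary (mean, SD, quantiles) of every matrix.  The run is
#' deterministic given the configuration and seed; on any stage failure the
#' partial outputs are removed and the error is re-signalled with a stage
#' label.
#'
#' @param config a configuration from [runConfig()].
#' @param series optional [RoiTimeSeries-class] overriding
#'   \code{config$input}.
#' @return invisibly, a named list of the written file paths.
#' @export
runPipeline <- function(config, series = NULL) {
  stopifnot(inherits(config, "nldfcConfig"))
  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  written <- character(0)
  out <- function(f) file.path(config$outDir, f)
  stage <- "setup"
  result <- tryCatch({
    set.seed(config$seed)
    stage <- "input"
    if (is.null(series)) {
      if (is.null(config$input)) stop("no input path and no series given")
      series <- readSeriesTable(config$input, config$delimiter,
                                tr = config$tr)
    }
    series <- .ensureZscored(series, quiet = TRUE)
    labs <- regionLabels(series)

    stage <- "events"
    sets <- lapply(labs, function(l)
      detectEvents(series, l, config$threshold, config$pre, config$post))
    names(sets) <- labs
    catalog <- lapply(sets, function(e)
      list(region = e@region, threshold = e@threshold, pre = e@pre,
           post = e@post, times = e@times, dropped = e@dropped))
    jsonlite::write_json(catalog, out("events.json"), auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, out("events.json"))

    stage <- "fc"
    report <- list(config = unclass(config),
                   nTimepoints = nTimepoints(series),
                   regions = labs,
                   eventCounts = lapply(sets, function(e) length(e@times)),
                   droppedEvents = lapply(sets, function(e) e@dropped))
    fcs <- list(pearson_full = fcMatrix(series, "pearson_full"))
    for (m in setdiff(config$fcMethods, "pearson_full"))
      fcs[[m]] <- suppressWarnings(
        fcMatrix(series, m, config$threshold, config$pre, config$post))
    for (m in names(fcs)) {
      f <- out(sprintf("fc_%s.tsv", sub("_full$", "", m)))
      .writeMatrixTsv(values(fcs[[m]]), f)
      written <- c(written, f)
      report$matrices[[paste0("fc_", m)]] <- c(
        .distSummary(values(fcs[[m]])),
        nUndefined = fcs[[m]]@nUndefined)
    }

    stage <- "directionality"
    eventFc <- fcs[[setdiff(names(fcs), "pearson_full")[1]]]
    if (!is.null(eventFc)) {
      asy <- asymmetry(eventFc)
      .writeMatrixTsv(asy@pairwise, out("asymmetry.tsv"))
      written <- c(written, out("asymmetry.tsv"))
      perRegion <- data.frame(region = labs, asymmetry = asy@perRegion)
      write.table(perRegion, out("asymmetry_per_region.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      written <- c(written, out("asymmetry_per_region.tsv"))
      report$matrices$asymmetry <- c(.distSummary(asy@pairwise),
                                     global = asy@global,
                                     nExcluded = asy@nExcluded)
      report$graph <- graphSummary(eventFc, config$edgeThreshold)
    }

    stage <- "delays"
    dp <- delayMatrix(series, "pearson_lag", maxLag = config$maxLag)
    de <- suppressWarnings(delayMatrix(
      series, "event_lag", threshold = config$threshold, pre = config$pre,
      post = config$post, windowMin = config$windowMin,
      windowMax = config$windowMax, clampAt = config$clampAt))
    .writeMatrixTsv(values(dp), out("delay_pearson.tsv"))
    .writeMatrixTsv(values(de), out("delay_event.tsv"))
    written <- c(written, out("delay_pearson.tsv"), out("delay_event.tsv"))
    report$matrices$delay_pearson <- .distSummary(values(dp))
    report$matrices$delay_event <- .distSummary(values(de))

    stage <- "report"
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    written <- c(written, out("report.json"))
    invisible(as.list(structure(written, names = basename(written))))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
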