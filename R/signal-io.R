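#' Read a regional time-series table
#'
#' Reads a delimited text table whose first row is a header of region labels
#' and whose remaining rows are one time point each.  Missing or non-numeric
#' cells are rejected: the event method assumes complete scans and no
#' imputation is attempted.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator; \code{"\t"} (default) or \code{","}.
#' @param tr repetition time in seconds to attach (default 1).
#' @return A [RoiTimeSeries-class] with \code{zscored = FALSE}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeSeriesTable(roiTimeSeries(cbind(A = 1:5, B = 5:1), tr = 2), f)
#' readSeriesTable(f, tr = 2)
#' @export
readSeriesTable <- function(path, delimiter = "\t", tr = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty file: ", path)
  split1 <- strsplit(lines, delimiter, fixed = TRUE)
  labels <- trimws(split1[[1L]])
  n <- length(labels)
  body <- split1[-1L]
  if (length(body) < 2L)
    stop("T >= 2 required: table body has ", length(body), " row(s)")
  widths <- lengths(body)
  if (any(widths != n))
    stop("ragged table: row ", which(widths != n)[1L] + 1L, " has ",
         widths[widths != n][1L], " fields, header has ", n)
  data <- matrix(NA_real_, nrow = length(body), ncol = n,
                 dimnames = list(NULL, labels))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]]))
    if (anyNA(v)) {
      cbad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   r + 1L, labels[cbad], body[[r]][cbad]))
    }
    data[r, ] <- v
  }
  roiTimeSeries(data, tr = tr, zscored = FALSE)
}

#' Write a regional time-series table
#'
#' Inverse of [readSeriesTable()]: writes the header of region labels and one
#' row per time point, at full double precision so a round-trip is
#' value-preserving.
#'
#' @param series a [RoiTimeSeries-class].
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeSeriesTable <- function(series, path, delimiter = "\t") {
  stopifnot(is(series, "RoiTimeSeries"))
  d <- seriesData(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = delimiter), con)
  body <- apply(d, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = delimiter))
  writeLines(body, con)
  invisible(path)
}

.colZscore <- function(d) {
  m <- colMeans(d)
  s <- sqrt(colMeans(sweep(d, 2L, m)^2))
  if (any(s == 0))
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(d)[s == 0], collapse = ", "))
  sweep(sweep(d, 2L, m), 2L, s, "/")
}

#' Standardise each region to zero mean and unit SD
#'
#' Subtracts each column's mean and divides by its population SD (the
#' \code{1/T} convention, so that the zero-lag autocovariance of a z-scored
#' series is exactly 1).  Event thresholds are expressed in these SD units.
#' The operation is idempotent.
#'
#' @param series a [RoiTimeSeries-class].
#' @return a z-scored [RoiTimeSeries-class] (\code{zscored = TRUE}).
#' @examples
#' z <- zscoreSeries(roiTimeSeries(cbind(A = c(1, 2, 3)), tr = 2))
#' seriesData(z)  # -1.2247, 0, 1.2247
#' @export
zscoreSeries <- function(series) {
  stopifnot(is(series, "RoiTimeSeries"))
  roiTimeSeries(.colZscore(seriesData(series)), tr = trSeconds(series),
                zscored = TRUE)
}

# Z-score the input unless flagged already standardised; used by every event
# operation so that raw tables can be passed directly (with a notice).
.ensureZscored <- function(series, quiet = FALSE) {
  if (isZscored(series)) return(series)
  if (!quiet) message("input not flagged z-scored; standardising columns")
  zscoreSeries(series)
}

#' Extract mean regional time series from a 4D image and an atlas
#'
#' For every nonzero integer label in the atlas volume, averages the 4D
#' image over that label's voxels at each time point, producing one column
#' per label (sorted ascending).  Inputs may be file paths to NIfTI images
#' (read with \pkg{RNifti}) or plain arrays; a 3D image is treated as a
#' single time point and rejected (T >= 2 is required downstream).
#'
#' @param image4d 4D numeric array or NIfTI path, x-y-z-time.
#' @param atlas 3D integer-valued array or NIfTI path on the same grid.
#' @param tr repetition time in seconds; if \code{NULL} and \code{image4d}
#'   is a NIfTI file, taken from the header's time-dimension pixdim. An
#'   explicit value takes precedence over the header (a mismatch warns).
#' @param labelPrefix prefix for the generated column names
#'   (default \code{"roi"}; label 3 becomes \code{"roi3"}).
#' @return a [RoiTimeSeries-class], one column per atlas label.
#' @export
extractAtlasSeries <- function(image4d, atlas, tr = NULL, labelPrefix = "roi") {
  headerTr <- NULL
  if (is.character(image4d)) {
    img <- RNifti::readNifti(image4d)
    pd <- attr(RNifti::niftiHeader(img), "pixdim")
    hd <- RNifti::niftiHeader(img)
    if (!is.null(hd$pixdim) && length(hd$pixdim) >= 5 && hd$pixdim[5] > 0)
      headerTr <- hd$pixdim[5]
    image4d <- as.array(img)
  }
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  image4d <- unclass(image4d); atlas <- unclass(atlas)
  if (length(dim(image4d)) != 4L)
    stop("image must be 4D (x, y, z, time)")
  if (!identical(dim(image4d)[1:3], dim(atlas)[1:3]) ||
      length(dim(atlas)) != 3L)
    stop("atlas grid ", paste(dim(atlas), collapse = "x"),
         " does not match image grid ",
         paste(dim(image4d)[1:3], collapse = "x"))
  if (any(abs(atlas - round(atlas)) > 1e-6))
    stop("atlas must be integer-valued")
  atlas <- as.integer(round(atlas))
  labs <- sort(unique(atlas[atlas != 0L]))
  if (length(labs) == 0L) stop("atlas contains no nonzero labels")
  if (!is.null(tr) && !is.null(headerTr) && abs(tr - headerTr) > 1e-6)
    warning(sprintf("supplied TR (%g s) overrides header TR (%g s)",
                    tr, headerTr))
  if (is.null(tr)) tr <- if (!is.null(headerTr)) headerTr else 1
  nt <- dim(image4d)[4L]
  flat <- matrix(image4d, ncol = nt)  # voxel x time
  out <- matrix(NA_real_, nrow = nt, ncol = length(labs),
                dimnames = list(NULL, paste0(labelPrefix, labs)))
  for (k in seq_along(labs))
    out[, k] <- colMeans(flat[atlas == labs[k], , drop = FALSE])
  roiTimeSeries(out, tr = tr, zscored = FALSE)
}
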