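#' Specification for the surrogate BOLD generator
#'
#' Collects every parameter of the surrogate generator in one validated
#' object.  Defaults emulate resting-state BOLD as seen after standard
#' preprocessing: TR 2.3 s, lag-1 autocorrelation 0.725 (midpoint of the
#' empirical 0.6-0.85 range for regional BOLD), hemodynamic-response-shaped
#' transient events (double-gamma, peak ~5 s, ~15 s total support) placed at
#' Poisson times, and optional directed couplings that copy a configurable
#' share of a driver's events into a receiver at a configurable (possibly
#' sub-sample) lag.
#'
#' @slot nRegions number of regions N.
#' @slot nTimepoints scan length T in samples.
#' @slot tr repetition time in seconds.
#' @slot noiseModel \code{"ar1"} (first-order autoregressive) or
#'   \code{"spectral"} (1/f^alpha shaping with random phases).
#' @slot rho lag-1 autocorrelation of the AR(1) noise, in (0, 1).
#' @slot alpha spectral exponent of the 1/f^alpha noise, > 0.
#' @slot eventRate expected events per scan per region (recycled to N).
#' @slot eventAmplitude peak event amplitude in noise-SD units.
#' @slot noiseScale SD of the additive noise (1 = z-scale before events).
#' @slot hrfPeak,hrfUndershoot,hrfDuration double-gamma response: time to
#'   peak, time to undershoot trough, and total support, all in seconds.
#' @slot refractory if TRUE (default) consecutive events of a region are at
#'   least one response duration apart, limiting overlap.
#' @slot couplings data.frame with columns \code{driver}, \code{receiver}
#'   (region indices), \code{lag} (TR units, real-valued), \code{share}
#'   (fraction of driver events copied, in [0, 1]) and \code{amplitude}.
#' @seealso [simulationSpec()], [genNoise()], [genCoupled()]
#' @export
setClass("SimulationSpec",
  representation(nRegions = "integer", nTimepoints = "integer",
                 tr = "numeric", noiseModel = "character", rho = "numeric",
                 alpha = "numeric", eventRate = "numeric",
                 eventAmplitude = "numeric", noiseScale = "numeric",
                 hrfPeak = "numeric", hrfUndershoot = "numeric",
                 hrfDuration = "numeric", refractory = "logical",
                 couplings = "data.frame")
)

setValidity("SimulationSpec", function(object) {
  if (object@nRegions < 1L) return("nRegions >= 1 required")
  if (object@nTimepoints < 2L) return("nTimepoints >= 2 required")
  if (object@tr <= 0) return("tr must be positive")
  if (!object@noiseModel %in% c("ar1", "spectral"))
    return("noiseModel must be 'ar1' or 'spectral'")
  if (object@noiseModel == "ar1" && (object@rho <= 0 || object@rho >= 1))
    return("rho must lie in (0, 1)")
  if (object@noiseModel == "spectral" && object@alpha <= 0)
    return("alpha must be > 0")
  if (any(object@eventRate < 0)) return("eventRate must be >= 0")
  if (object@hrfDuration <= object@hrfPeak)
    return("hrfDuration must exceed hrfPeak")
  cp <- object@couplings
  if (nrow(cp)) {
    need <- c("driver", "receiver", "lag", "share", "amplitude")
    if (!all(need %in% names(cp)))
      return(paste("couplings needs columns:", paste(need, collapse = ", ")))
    if (any(cp$driver < 1 | cp$driver > object@nRegions |
            cp$receiver < 1 | cp$receiver > object@nRegions))
      return("coupling driver/receiver indices out of range")
    if (any(cp$share < 0 | cp$share > 1)) return("shares must lie in [0, 1]")
    if (any(abs(cp$lag) > 8)) return("coupling lag outside the delay search window")
  }
  TRUE
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d region(s) x %d samples, TR = %g s, noise = %s, %d coupling(s)\n",
    object@nRegions, object@nTimepoints, object@tr,
    if (object@noiseModel == "ar1") sprintf("AR(1) rho = %g", object@rho)
    else sprintf("1/f^%g", object@alpha),
    nrow(object@couplings)))
})

#' Construct a SimulationSpec
#'
#' @param nRegions,nTimepoints,tr scan geometry (defaults: 2 regions,
#'   104 samples — a 4-minute scan at TR 2.3 s).
#' @param noiseModel \code{"ar1"} or \code{"spectral"}.
#' @param rho AR(1) lag-1 autocorrelation (default 0.725).
#' @param alpha spectral exponent for \code{"spectral"} noise (default 1).
#' @param eventRate expected events per scan per region (default 0: pure
#'   noise).
#' @param eventAmplitude peak event amplitude in noise-SD units (default 3).
#' @param noiseScale additive-noise SD relative to the unit event scale
#'   (default 1).
#' @param hrfPeak,hrfUndershoot,hrfDuration response shape in seconds
#'   (defaults 5, 11 and 15).
#' @param refractory enforce one response duration between a region's own
#'   events (default TRUE).
#' @param couplings data.frame (\code{driver}, \code{receiver}, \code{lag},
#'   \code{share}, \code{amplitude}); see [SimulationSpec-class].
#' @return a validated [SimulationSpec-class].
#' @examples
#' simulationSpec(nRegions = 3, eventRate = 8)
#' @export
simulationSpec <- function(nRegions = 2L, nTimepoints = 104L, tr = 2.3,
                           noiseModel = c("ar1", "spectral"), rho = 0.725,
                           alpha = 1, eventRate = 0, eventAmplitude = 3,
                           noiseScale = 1, hrfPeak = 5, hrfUndershoot = 11,
                           hrfDuration = 15, refractory = TRUE,
                           couplings = NULL) {
  if (is.null(couplings))
    couplings <- data.frame(driver = integer(0), receiver = integer(0),
                            lag = numeric(0), share = numeric(0),
                            amplitude = numeric(0))
  new("SimulationSpec", nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints), tr = tr,
      noiseModel = match.arg(noiseModel), rho = rho, alpha = alpha,
      eventRate = rep_len(as.numeric(eventRate), nRegions),
      eventAmplitude = eventAmplitude, noiseScale = noiseScale,
      hrfPeak = hrfPeak, hrfUndershoot = hrfUndershoot,
      hrfDuration = hrfDuration, refractory = refractory,
      couplings = couplings)
}

#' Double-gamma hemodynamic response
#'
#' The canonical two-gamma shape: a positive gamma density peaking at
#' \code{peak} seconds minus a scaled gamma density peaking at
#' \code{undershoot} seconds, truncated at \code{duration} seconds and
#' normalised to unit maximum.  With the defaults the response rises over
#' ~5 s, undershoots around 11 s and has died out by 15 s, matching the
#' 10-15 s timescale of transient BOLD events.
#'
#' @param tSeconds time(s) since event onset, in seconds.
#' @param peak time-to-peak of the positive lobe (s).
#' @param undershoot time of the undershoot trough (s).
#' @param duration total support (s); the response is 0 outside
#'   [0, duration].
#' @param undershootRatio amplitude ratio of undershoot to peak lobe
#'   (default 1/6).
#' @return response value(s), unit peak amplitude.
#' @export
doubleGammaHrf <- function(tSeconds, peak = 5, undershoot = 11,
                           duration = 15, undershootRatio = 1 / 6) {
  # gamma density with unit scale peaks at shape - 1
  h <- function(t) dgamma(t, shape = peak + 1, scale = 1) -
    undershootRatio * dgamma(t, shape = undershoot + 1, scale = 1)
  # unit maximum: the undershoot term shifts the true argmax slightly off
  # `peak`, so normalise against a dense grid rather than h(peak)
  peakVal <- max(h(seq(0, duration, by = 1e-3)))
  out <- ifelse(tSeconds < 0 | tSeconds > duration, 0,
                h(tSeconds) / peakVal)
  # cosine-taper the last fifth of the support so the response reaches zero
  # smoothly (a truncation step would inject a spurious local extremum)
  taperFrom <- duration * 0.8
  inTaper <- tSeconds > taperFrom & tSeconds <= duration
  out[inTaper] <- out[inTaper] *
    (0.5 + 0.5 * cos(pi * (tSeconds[inTaper] - taperFrom) /
                       (duration - taperFrom)))
  out
}

.ar1 <- function(T, rho) {
  x <- numeric(T)
  x[1L] <- rnorm(1)                     # stationary start (unit variance)
  innov <- rnorm(T - 1L) * sqrt(1 - rho^2)
  for (t in 2:T) x[t] <- rho * x[t - 1L] + innov[t - 1L]
  x
}

.spectralNoise <- function(T, alpha) {
  # shape white Gaussian noise to a 1/f^alpha amplitude spectrum
  f <- fft(rnorm(T))
  freq <- c(1e-12, seq_len(T - 1L))
  freq <- pmin(freq, T - freq)          # fold to physical frequencies
  f <- f * freq^(-alpha / 2)
  f[1L] <- 0
  Re(fft(f, inverse = TRUE)) / T
}

#' Generate autocorrelated surrogate noise
#'
#' Per-region independent noise realisations: either AR(1),
#' x_t = rho * x_{t-1} + sqrt(1 - rho^2) * eps_t with standard-normal
#' innovations (stationary unit variance), or Gaussian noise shaped to a
#' 1/f^alpha amplitude spectrum with random phases.  The output is z-scored.
#' Deterministic for a fixed R random seed (\code{set.seed} before calling).
#'
#' @param spec a [SimulationSpec-class]; only the geometry and noise fields
#'   are used.
#' @return a z-scored [RoiTimeSeries-class].
#' @examples
#' set.seed(7)
#' genNoise(simulationSpec(nRegions = 4, nTimepoints = 200))
#' @export
genNoise <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  T <- spec@nTimepoints
  d <- vapply(seq_len(spec@nRegions), function(i)
    if (spec@noiseModel == "ar1") .ar1(T, spec@rho)
    else .spectralNoise(T, spec@alpha),
    numeric(T))
  colnames(d) <- paste0("R", seq_len(spec@nRegions))
  zscoreSeries(roiTimeSeries(d, tr = spec@tr))
}

# Poisson event onsets (seconds) over a scan, optionally with a refractory
# gap of one response duration; events too close to the scan end are not
# placed so the full response fits.
.eventOnsets <- function(rate, scanSeconds, hrfDuration, refractory) {
  usable <- max(0, scanSeconds - hrfDuration)
  if (rate <= 0 || usable <= 0) return(numeric(0))
  n <- rpois(1, rate)
  if (n == 0L) return(numeric(0))
  t <- sort(runif(n, 0, usable))
  if (refractory && length(t) > 1L) {
    keep <- t[1L]
    for (x in t[-1L]) if (x - keep[length(keep)] >= hrfDuration)
      keep <- c(keep, x)
    t <- keep
  }
  t
}

#' Generate coupled surrogate BOLD with known ground truth
#'
#' Builds N regional signals: each region receives its own
#' hemodynamic-response-shaped events at Poisson onset times (rate
#' \code{eventRate} per scan), every coupling copies a Bernoulli
#' (\code{share}) subset of the driver's events into the receiver shifted by
#' \code{lag} TRs — sub-sample lags are realised exactly by sampling the
#' continuous response at shifted times, not by interpolating noise — and
#' independent autocorrelated noise of SD \code{noiseScale} is added.
#' Columns are z-scored.  The returned ground truth carries every onset and
#' the imposed per-coupling lag and share, so estimator recovery can be
#' scored against it.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with \code{series} (z-scored [RoiTimeSeries-class]) and
#'   \code{truth}: \code{onsets} (per-region list, seconds),
#'   \code{onsetSamples} (nearest 1-based sample indices) and
#'   \code{couplings} (the coupling table of \code{spec} with a
#'   \code{nCopied} column appended).
#' @examples
#' set.seed(11)
#' sp <- simulationSpec(nRegions = 2, nTimepoints = 300, eventRate = 8,
#'                      couplings = data.frame(driver = 1, receiver = 2,
#'                                             lag = 1.5, share = 1,
#'                                             amplitude = 3))
#' sim <- genCoupled(sp)
#' sim$truth$couplings
#' @export
genCoupled <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  T <- spec@nTimepoints; tr <- spec@tr
  tGrid <- (seq_len(T) - 1L) * tr
  scanSeconds <- T * tr
  clean <- matrix(0, T, spec@nRegions)
  onsets <- vector("list", spec@nRegions)
  # the refractory gap spans one delay-search window (15 TRs) or the
  # response duration, whichever is longer, plus the largest coupling lag:
  # consecutive events and their lagged copies never share a search window
  gap <- max(spec@hrfDuration, 15 * tr) +
    if (nrow(spec@couplings)) max(abs(spec@couplings$lag)) * tr else 0
  for (r in seq_len(spec@nRegions)) {
    onsets[[r]] <- .eventOnsets(spec@eventRate[r], scanSeconds, gap,
                                spec@refractory)
    for (t0 in onsets[[r]])
      clean[, r] <- clean[, r] + spec@eventAmplitude *
        doubleGammaHrf(tGrid - t0, spec@hrfPeak, spec@hrfUndershoot,
                       spec@hrfDuration)
  }
  cp <- spec@couplings
  nCopied <- integer(nrow(cp))
  if (nrow(cp)) for (ci in seq_len(nrow(cp))) {
    drv <- cp$driver[ci]; rcv <- cp$receiver[ci]
    copy <- runif(length(onsets[[drv]])) < cp$share[ci]
    nCopied[ci] <- sum(copy)
    for (t0 in onsets[[drv]][copy])
      clean[, rcv] <- clean[, rcv] + cp$amplitude[ci] *
        doubleGammaHrf(tGrid - t0 - cp$lag[ci] * tr, spec@hrfPeak,
                       spec@hrfUndershoot, spec@hrfDuration)
  }
  if (spec@noiseScale > 0) {
    noise <- vapply(seq_len(spec@nRegions), function(i)
      if (spec@noiseModel == "ar1") .ar1(T, spec@rho)
      else .spectralNoise(T, spec@alpha), numeric(T))
    noise <- scale(noise)[, , drop = FALSE]
    clean <- clean + spec@noiseScale * noise
  }
  colnames(clean) <- paste0("R", seq_len(spec@nRegions))
  series <- zscoreSeries(roiTimeSeries(clean, tr = tr))
  truthCp <- cbind(cp, nCopied = nCopied)
  list(series = series,
       truth = list(onsets = onsets,
                    onsetSamples = lapply(onsets, function(o)
                      as.integer(round(o / tr)) + 1L),
                    couplings = truthCp))
}
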