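---
title: "Event-triggered directed functional connectivity: methods and design notes"
author: "nldFC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-triggered directed functional connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nldFC)
```

## The method in brief

Conventional functional connectivity (FC) correlates two regions' entire
BOLD time series, which is symmetric by construction and blind to timing.
This package instead works with the brief, large-amplitude excursions of the
signal — "events" — on the premise that most of the FC information is
carried by them:

1. **Events.** Each regional series is z-scored (zero mean, unit
   *population* SD, so thresholds are in SD units).  An event of a *source*
   region is an upward crossing of a threshold $\theta$ (default 1 SD): the
   first sample $t$ with $x(t-1) < \theta \le x(t)$.  A window of `pre` TRs
   before to `post` TRs after the crossing (defaults 2 and 4, about 4.6 s
   and 9.2 s at TR 2.3 s — the span of the hemodynamic response) cuts the
   *source segment*; segments of every other region cut *at the same times*
   are *target segments*.
2. **Correlations.**  Five estimators are available: full-series Pearson
   $r_P$; the per-event correlation $r_E^{(k)}$ of the $k$-th source/target
   segment pair; their mean $\bar r_E$; the correlation $r_C$ of the
   concatenated segments; and the correlation $r_E$ of the *average* source
   event with the average target event, which is the package default.
   Because region $i$'s event set differs from region $j$'s, the event
   estimators are directional: $r_E(i,j) \ne r_E(j,i)$ in general.
3. **Directionality.**  Two complementary measures: the correlation
   asymmetry $D(i,j) = r_E(i,j) - r_E(j,i)$ (with per-region row sums and a
   global sum, the latter zero by antisymmetry over a complete matrix), and
   the shared-event ratio — the fraction of $i$'s events at which $j$ is
   also at/above threshold, normalised by $i$'s event count and therefore
   asymmetric.
4. **Delays.**  Two routes to inter-regional lags.  The cross-covariance
   route evaluates $C_{i,j}(\tau) = \frac1T\sum_t x_i(t+\tau)\,x_j(t)$ on
   integer lags, takes the extremum of $|C|$ and refines it with a
   three-point parabolic fit; the resulting matrix is exactly antisymmetric.
   The event route matches, for each source event, the peak of the source
   segment against the closest peak of the target signal inside a window of
   $[-6, +8]$ TRs around the crossing, both peaks refined parabolically;
   the per-event lags $\tau^{(k)}$, their mean $\bar\tau$, and the delay
   between average event waveforms are reported.  The event-delay matrix is
   *not* antisymmetric, because the two regions' event sets differ — that
   residual is signal, not artifact.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 1 | SD | event detection level; results are typically stable over 1–2 SD |
| `pre`, `post` | 2, 4 | TR | event window; `windowFromSeconds()` converts from seconds with floor rounding |
| `windowMin`, `windowMax` | −6, +8 | TR | event-delay search window around the crossing |
| `clampAt` | 6 | TR | lag assigned when the target peak sits on the window edge |
| `maxLag` | 10 | TR | half-width of the cross-covariance lag search |
| `edgeThreshold` | 0.5 | — | absolute-correlation cutoff for graph summaries |
| `tolerance` | 0 | TR | half-width for "simultaneous" in the shared-event ratio |

The asymmetric search window with a symmetric clamp is deliberate: the
search extends to +8 TRs, but an edge peak is assigned exactly −6 or +6 and
skips parabolic refinement, whose extrapolation beyond the window would be
unbounded.

## Numerical conventions and tie rules

Several discrete conventions are underdetermined by the method's
description; the package fixes them as follows and treats them as part of
the contract (they are asserted by the test suite):

* **z-scoring** divides by the population SD ($1/T$), so the zero-lag
  autocovariance of a z-scored series is exactly 1.
* **Crossing timing** is the first sample at/above threshold.  No minimum
  inter-event separation is imposed; overlapping windows are allowed.
  Events whose window does not fit inside the scan are dropped (not padded)
  and counted.
* **Negative lags** of the cross-covariance are defined through the
  reversal identity $C_{i,j}(-\tau) = C_{j,i}(\tau)$, and the Pearson-delay
  matrix fills $\tau(j,i) = -\tau(i,j)$ from the upper triangle, making
  antisymmetry exact rather than approximate.
* **Parabolic refinement** uses
  $\delta = \tfrac12 (y_- - y_+)/(y_- - 2y_0 + y_+)$, returns 0 when the
  denominator is below $10^{-12}$ (collinear points), and clamps
  $\delta$ to $[-1, 1]$.
* **Local peaks** are strictly greater than both neighbours; plateaus take
  their leftmost sample.  If a search window holds no interior peak, the
  window maximum is used, and a maximum on the window edge triggers the
  clamped-lag rule.
* **Peak matching is anchored at the source peak.**  The source event's
  peak (the maximum inside the event window, parabolically refined) is
  centred at time zero, and the target peak *closest to it* is chosen —
  ties resolve to the earlier peak.  Anchoring at the real-valued refined
  peak rather than the integer crossing both matches the peak-to-peak
  definition of the delay and makes exact distance ties (which would
  otherwise systematically favour the earlier side) a measure-zero event.
* **Undefined correlations** (constant segments) are excluded from
  averages with a count, never propagated; regions with zero usable events
  yield NA rows with a warning.
* **Graph summaries** symmetrise by the elementwise maximum of
  $|r(i,j)|$ and $|r(j,i)|$, report the global clustering coefficient
  (transitivity) and average shortest path over connected pairs only,
  counting disconnected pairs.

## The surrogate generator

`genNoise()` and `genCoupled()` produce BOLD-like test data with known
ground truth, which is how every estimator here is validated (parameter
recovery rather than comparison against an external implementation).

* **Noise.**  AR(1) with lag-1 autocorrelation `rho` (default 0.725, the
  midpoint of the 0.6–0.85 range reported for regional BOLD), or Gaussian
  noise shaped to a $1/f^\alpha$ amplitude spectrum.  AR(1) reproduces the
  empirical threshold-crossing statistics of resting BOLD — the package's
  acceptance script checks that z-scored AR(1) surrogates at $\rho = 0.725$,
  104 samples (4 minutes at TR 2.3 s) yield on the order of 8–9 upward
  1-SD crossings per scan, against the published 8.5 ± 2.8.
* **Events.**  A double-gamma response (peak 5 s, undershoot trough
  ~11 s, support 15 s) placed at Poisson onset times.  The response is
  cosine-tapered over the last fifth of its support: a hard truncation
  leaves a step to zero whose junction injects spurious local maxima into
  the closest-peak search.
* **Coupling.**  Each coupling copies a Bernoulli(`share`) subset of the
  driver's events into the receiver, shifted by `lag` TRs.  Sub-sample lags
  are exact: the continuous response is sampled at shifted times rather
  than interpolating discrete data.
* **Refractory period.**  Consecutive events of a region are separated by
  at least one delay-search window (15 TRs, or the response duration if
  longer) plus the largest coupling lag.  The longer reading matters: with
  a response-length gap only, the lagged copy of one event still ends
  inside the next event's search window and the imposed lag stops being
  identifiable per event.

### Study conditions used by the recovery tests

The recovery suites fix their conditions once: coupled pairs with event
amplitude 3, spectral $1/f^5$ noise at scale 0.25, scans of 400 samples
(~15 min at TR 2.3 s; 700 samples for the directionality contrast), event
rates of 13–16 per scan.  Two of these choices deserve explanation:

* *Why spectral noise for recovery but AR(1) for crossing statistics?*
  The closest-peak delay search takes the nearest local maximum
  "irrespective of its size", so it presumes signals whose local maxima are
  event-driven — which measured BOLD, being hemodynamically low-pass
  filtered, approximates well.  An AR(1) process matches the *lag-1
  autocorrelation* of BOLD but is far rougher at the sample scale (about
  0.27 strict local maxima per sample, versus rare maxima for the smooth
  spectral model), so it is the right surrogate for crossing counts and the
  wrong one for peak matching.  Each suite uses the model matching the
  property it probes.
* *Why a ±1 TR tolerance in the directionality recovery?*  The imposed
  coupling is lag-0 co-activation of whole events, not sample-exact
  threshold coincidence: at the source's crossing sample the receiver's
  copy sits exactly at the knife's edge of its own threshold (the two
  regions are z-scored by different SDs), so the sample-exact ratio is a
  coin flip per event.  The one-TR window asks the scientifically intended
  question — was the receiver excursion co-occurring — and the function's
  default remains the strict `tolerance = 0`.

### What the generator does not emulate

Scanner drift and motion artifacts, physiological (cardiac/respiratory)
nuisance structure, spatial correlation between regions beyond the explicit
couplings, HRF variability across regions, and any preprocessing pipeline
effects.  Passing recovery tests therefore show that the estimators invert
the generator's forward model at realistic noise levels — not that they are
robust to every artifact of real scans.

## Known limitations

* Event-based correlations on 7-sample windows are noisy estimators; their
  null distribution is much wider than full-series Pearson values at the
  same scan length (a property the test suite checks).  No small-sample
  bias correction is applied.
* The shared-event ratio at `tolerance = 0` is sensitive to the relative
  SDs of the two regions, as discussed above.
* The closest-peak delay degrades when genuine lags push the target peak
  more than ~4 TRs from the source peak while competing local maxima exist
  nearer — large lags are reliably recovered only in smooth, mildly noisy
  signals.
* Group-level statistics (t-maps, cluster correction) are out of scope;
  the pipeline stops at per-scan matrices and distribution summaries.
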