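# nldFC — event-triggered directed dynamic functional connectivity

`nldFC` analyses functional MRI BOLD time series through their brief,
large-amplitude events rather than through whole-series correlations.  It is
aimed at researchers studying resting-state or task fMRI who want, beyond the
usual symmetric Pearson functional-connectivity (FC) matrix, (a) *directed*
connectivity and (b) *temporal delays* between regions — at the cost of
nothing more than thresholding and linear correlations.

## The method

For each z-scored regional signal $x_i(t)$ (thresholds in SD units), events
are the upward crossings of a threshold $\theta$ (default 1 SD).  A window of
2 TRs before to 4 TRs after each crossing cuts the **source segments** of
region $i$; segments of every other region $j$ cut at the *same* times are
the **target segments**.  On these the package computes:

* **Correlations** — full-series Pearson $r_P(i,j)$; per-event correlations
  $r_E^{(k)}(i,j)$ and their mean $\bar r_E(i,j)$; the correlation $r_C(i,j)$
  of concatenated segments; and the correlation $r_E(i,j)$ of the *average*
  source event with the average target event (the default).  Event
  estimators are directional: $r_E(i,j) \ne r_E(j,i)$ because the two
  regions' event sets differ.
* **Directionality** — the correlation asymmetry
  $D(i,j) = r_E(i,j) - r_E(j,i)$ (pairwise, per-region and global sums), and
  the shared-event ratio: the fraction of $i$'s events at which $j$ is also
  above threshold.
* **Delays** — lagged cross-covariance
  $C_{i,j}(\tau) = \frac1T \sum_t x_i(t+\tau) x_j(t)$ with a three-point
  parabolic refinement of its extremum (an exactly antisymmetric lag
  matrix), and an event-based delay: per event, the time from the source
  segment's peak to the closest peak of the target signal within
  $[-6, +8]$ TRs of the crossing, both peaks parabolically refined, edge
  peaks clamped to $\pm 6$ TR.
* **Surrogates** — a seed-deterministic generator of BOLD-like data
  (AR(1) or $1/f^\alpha$ noise, double-gamma response events, directed
  couplings with known sub-sample lag and event share) used to validate
  every estimator by parameter recovery.

See `vignettes/event-connectivity.Rmd` for conventions, tie rules and
design rationale.

## Worked example

Two coupled regions (every event of R1 is copied into R2 at a lag of
+1.5 TR) plus one independent region:

```r
library(nldFC)
set.seed(11)
sp <- simulationSpec(nRegions = 3, nTimepoints = 400, tr = 2.3,
                     noiseModel = "spectral", alpha = 5, noiseScale = 0.25,
                     eventRate = c(10, 0, 10),
                     couplings = data.frame(driver = 1, receiver = 2,
                                            lag = 1.5, share = 1,
                                            amplitude = 3))
sim <- genCoupled(sp)

detectEvents(sim$series, "R1")
#> EventSet: region 'R1', 7 events (theta = 1 SD, window -2/+4 TR, 0 dropped)

round(values(fcMatrix(sim$series, "event_average")), 3)
#>       R1    R2     R3
#> R1 1.000 0.100 -0.081
#> R2 0.117 1.000  0.002
#> R3 0.062 0.022  1.000

ed <- eventDelay(sim$series, "R1", "R2")
round(ed$perEvent, 2)
#> [1] 1.50 1.42 1.60 1.61 1.43 1.40 1.61
round(ed$mean, 3)
#> [1] 1.51
```

The zero-lag event correlation between the coupled pair (0.100) is barely
above the independent pair's, because a 1.5-TR shift decorrelates
7-sample event windows — but the event delay pinpoints the imposed lag:
every per-event estimate lies within 0.11 TR of the true 1.5, mean 1.51.
This is the regime the method is built for: connectivity that is invisible
at zero lag but sharp in the time domain.

A shell interface covering the same pipeline is installed at
`inst/exec/nldfc` (subcommands `simulate`, `events`, `fc`, `direction`,
`delay`, `graph`, `run`).

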