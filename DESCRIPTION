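Package: nldFC
Title: Event-Triggered Directed Dynamic Functional Connectivity for BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects large-amplitude events in z-scored BOLD (blood
    oxygenation level dependent) time series by upward threshold crossings,
    extracts source and target event segments, and computes event-based
    functional-connectivity estimators that are in general asymmetric,
    yielding directed connectivity. Also provides correlation-asymmetry and
    shared-event directionality measures, inter-regional temporal delays by
    lagged cross-covariance with parabolic sub-sample interpolation and by
    event-based closest-peak matching, thresholded-graph summaries, atlas
    extraction of regional time series from 4D NIfTI images, and a
    seed-deterministic generator of BOLD-like surrogate data (autocorrelated
    noise, hemodynamic-response-shaped events, directed coupling with known
    lag) for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
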