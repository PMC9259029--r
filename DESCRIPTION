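Package: gazestab
Title: Quantification of Compensatory Head-Roll Responses from
    Stimulus-Response Time Series
Version: 0.1.0
Authors@R:
    person("Gazestab", "Maintainers", email = "maintainers@gazestab.invalid",
           role = c("aut", "cre"))
Description: Tools for quantifying compensatory head stabilization from
    sinusoidal body-roll stimulus and head-response angle time series, as
    recorded in tethered-insect roll assays. Provides a seeded synthetic
    trial generator with known ground-truth gain and phase (including
    wingbeat-frequency contamination, low-frequency head wobble, and an
    optional delayed multisensory feedback-loop simulator), zero-phase
    Butterworth preprocessing with ramp-segment exclusion, per-trial
    response metrics (Fourier amplitude-ratio gain, cross-correlation and
    FFT phase estimators, polar compensation error, magnitude-squared
    coherence), condition-level summaries (circular medians, 95%
    confidence ellipses), the non-parametric tests used in this assay
    family (paired Wilcoxon signed-rank, Wilcoxon rank-sum,
    Kruskal-Wallis with Nemenyi post hoc), free-flight bout metrics, and
    a command-line pipeline for reproducible simulate-analyze-compare
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
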