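---
title: "Quantifying compensatory head roll: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compensatory head roll: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazestab)
```

## The measurement problem

Flying insects stabilize their gaze by counter-rotating the head against
imposed body rotations. In the tethered roll assay this package supports, a
moth's body is rolled sinusoidally about its longitudinal axis
(±30° at 2 or 6 Hz, 8 cycles, filmed at 1200 frames/s) while the head is free
to move. Two angle time series describe each trial: the thorax roll angle
$\theta_{thorax}(t)$ (the stimulus) and the head-relative-to-thorax angle
$\theta_{head-thorax}(t) = \theta_{head} - \theta_{thorax}$ (the response).
A head that perfectly cancels the imposed roll satisfies
$\theta_{head-thorax} = -\theta_{thorax}$.

Per trial, the response is summarized at the stimulus frequency $f$ by

* **gain** $r$ — Fourier amplitude of the response at $f$ over the Fourier
  amplitude of the stimulus at $f$;
* **phase** $\theta$ — angular offset between response and stimulus, with
  the delay-positive convention under which a response lagging by a quarter
  period scores 90° and perfect compensation scores 180°;
* **compensation error**
  $\varepsilon = \sqrt{1 + r^2 + 2 r \cos\theta}$, the Euclidean distance in
  the polar $(r, \theta)$ plane between the measured point and the
  perfect-stabilization point $(1, 180°)$. $\varepsilon = 0$ is perfect
  compensation, $\varepsilon = 1$ arises with no response at all ($r = 0$),
  $\varepsilon = 2$ is a fully in-phase unit response; for $r \le 1$,
  $\varepsilon \in [0, 2]$. Because gain and phase are inherently linked,
  $\varepsilon$ is the quantity compared statistically across conditions;
* **magnitude-squared coherence** at $f$, a [0, 1] measure of how linearly
  the response follows the stimulus.

## Phase conventions and the two estimators

Phase is estimated two ways and both are reported:

1. **Cross-correlation lag** (the primary method): the lag maximizing the
   stimulus–response cross-correlation, restricted to ±1 stimulus period
   (sinusoidal cross-correlation is periodic, so a wider search is
   ill-posed), with ties broken toward the smallest |lag|, converted via
   $\mathrm{phase} = 360° \cdot f \cdot \Delta t$. Its resolution is the lag
   grid, $360 f / f_s$ degrees (0.6° at 2 Hz, 1200 Hz sampling). The
   correlation is computed circularly over the whole-cycle window, which is
   exact for the windowed sinusoid and free of end effects.
2. **FFT phase** (the cross-check): $\arg S(f) - \arg R(f)$ at the exact DFT
   bin, continuous (no lag quantization).

Both estimators share one sign convention, fixed by the requirement that a
*delayed* response have *positive* phase. The synthetic generator uses the
matching convention, $\theta_{head-thorax}(t) = r A \sin(2\pi f t - \phi)$,
so estimators recover the generative $\phi$ exactly; with $\phi = 180°$ and
no noise this is exactly $-\theta_{thorax}$ over the sinusoidal segment.

A trial with gain below `min_gain_for_phase` (default 0.05) has no
interpretable phase: the phase fields are `NA` with flag
`phase_undefined`. Such trials keep their compensation error (which is ~1
regardless of phase when $r \approx 0$) and are excluded from circular
medians of phase.

## The synthetic world

The generator ([`response_model()`]/[`generate_response()`]) emulates what
the assay's videos contain, with known ground truth:

| parameter | default | why |
|---|---|---|
| gain, phase | 0.6, 177.6° | typical well-lit low-frequency compensation regime |
| wingbeat tone | 2° at 30 Hz | wingbeat-frequency contamination of head markers; amplitude per the generator's specification examples |
| head wobble | 0.5° at 12 Hz | small head oscillation distinct from wingbeat, visible in recordings of this assay family |
| white noise | 0.5° (sd) | digitization and residual broadband noise |
| stimulus | ±30°, 2 or 6 Hz, 8 cycles, 1200 Hz | assay protocol |

Tone phases are drawn uniformly per trial from the seeded generator; noise
is Gaussian. One integer seed fixes a trial bit-for-bit.

What the generator does **not** emulate: gain/phase drift within a trial,
non-sinusoidal (saccadic) head movements, marker-tracking dropouts,
animal-to-animal correlation structure beyond the generative parameters, and
any closed-loop dependence of the response on the head's own state. A green
parameter-recovery test therefore establishes that the estimators are
unbiased and precise *under this stated world*, not that the experimental
medians of any particular animal cohort are reproduced.

The stimulus replaces its first and last quarter cycle with linear ramps
(0 → +A, −A → 0 over $1/(4f)$ s) so onset/offset accelerations stay bounded;
the ramps preserve the sinusoid's mean absolute angular speed $4 A f$
(240°/s and 720°/s for the two assay frequencies).

An optional feedback-loop simulator ([`simulate_feedback_loop()`]) packages
the proposed two-channel control structure — visual and antennal
mechanosensory channels, each a pure gain and delay, summed into a
sign-inverted head command through a first-order neck filter. This is a
declared extrapolation: no functional forms are established for this system,
and whether the channels sense angle or angular velocity is exposed as a
configuration switch (`channel_input`) without any claim of fidelity. Delays
are rounded to whole samples and the neck filter uses the exact exponential
update, so the simulator's discrete transfer function is available in closed
form ([`feedback_frequency_response()`]) and the tests hold the simulator to
it at machine-level tolerance.

## Numerical choices

* **Filtering.** A 7th-order Butterworth low-pass at 25 Hz removes the
  ~30 Hz wingbeat tone. It is applied zero-phase (forward–backward): a
  causal pass's group delay would bias the cross-correlation lag. "7th
  order" is the designed single-pass order; the double pass squares the
  magnitude response (|H(30 Hz)|² ≈ 0.072, i.e. >22 dB suppression, while
  2 and 6 Hz pass within 10⁻⁸ of unity). Both series are filtered
  identically, so any residual phase effect cancels in the difference.
  Whether the thorax series was filtered in the original workflow is not
  documented; both-filtered is adopted here for exactly that cancellation
  property. Edge transients are controlled by odd-reflection padding sized
  so the slowest pole decays below 10⁻¹³, plus steady-state filter
  initialisation.
* **Analysis window.** The ramp quarter-cycles are excluded, then the
  remainder is trimmed to whole stimulus cycles so $f$ sits exactly on the
  DFT grid (leakage-free amplitudes without interpolation). The whole-cycle
  window is centered in the available span: the spare half cycle becomes a
  symmetric guard interval in which the filter's smearing of the
  ramp/sinusoid junction decays. With a left-aligned window the noise-free
  generative gain identity is met only to ~7·10⁻⁶ relative; centered, to
  ~3·10⁻⁸.
* **Coherence.** Welch averaging with Hann-tapered, 50%-overlapping
  segments of one stimulus cycle (13 segments on a 7-cycle window). One
  cycle rather than two is deliberate: with 2-cycle segments only 6
  segments fit the assay-scale record and the *null* coherence expectation
  (independent noise) is ≈ 0.20 — measured 0.211 over 2000 seeds here and
  0.196 with an independent reference implementation — which would make a
  noise-only response indistinguishable from weak coherence. With 1-cycle
  segments the null mean drops to ≈ 0.12 while a noise-free linear response
  still scores exactly 1. Single-segment estimates (identically 1) are
  refused.
* **Exact vs approximate tests.** The paired signed-rank test uses the
  exact null distribution for ≤ 25 tie-free pairs (two-sided p is the
  doubled tail; at n = 8 with uniformly signed differences this floors at
  2/2⁸ = 0.0078125), otherwise a tie/zero-corrected normal approximation
  with continuity correction. The rank-sum test is exact for tie-free
  groups below 50, tie-corrected normal otherwise. The Kruskal–Wallis H is
  tie-corrected with a χ²(k−1) p; the Nemenyi post hoc converts mean-rank
  differences to Studentized-range tail probabilities
  ($P(Q_k > q\sqrt{2})$), which for k = 2 reduces to the two-sided normal p
  and is conservative for k > 2. Whether the original analyses used exact
  or approximate p values is not documented; both paths are provided and
  neither is asserted as the original choice.
* **Circular median.** The sample angle minimizing the summed minimal-arc
  distance, restricted to observed angles with ties broken toward the
  smallest angle — deterministic and rotation-equivariant up to ties.
* **Confidence ellipse.** The cited construction gives no parameters, so
  the standard sample-covariance ellipse is used: polar points are mapped to
  Cartesian $(r\cos\theta, r\sin\theta)$, and the mean/covariance ellipse is
  scaled by the χ²(2) quantile at 95% coverage. At least 3 non-collinear
  points are required. Note that xcorr-phase quantization can collapse a
  tight cluster onto one ray (exactly collinear); the FFT phase is the
  natural choice when an ellipse of a low-noise synthetic cohort is wanted.
* **Flight bouts.** Duration = (landing − takeoff) − skid/crawl time,
  *then* rounded to the nearest second (the videos' effective timing
  resolution), then used as the collision-rate denominator — so rate values
  inherit the discretization.
* **Degenerate inputs.** Flat (zero-variance) series raise a classed
  condition (`gazestab_flat_series`) rather than returning 0°; zero
  stimulus amplitude at $f$ is an error (nothing to reference); all-zero
  paired differences and empty groups are errors, not p = 1.

## Tunable parameters that matter

| parameter | default | unit | notes |
|---|---|---|---|
| `filter_order`, `filter_cutoff` | 7, 25 | –, Hz | assay's published filter; cutoff must stay below Nyquist/2-ish of wingbeat separation |
| `min_gain_for_phase` | 0.05 | gain | below it phase is flagged undefined; well under the smallest generative gain tested (0.1) |
| `psd_config(segment_cycles, overlap)` | 1, 0.5 | cycles, fraction | see coherence rationale above |
| `phase_method` | `"xcorr"` | – | estimator feeding ε; `"fft"` is the cross-check |
| `sem_method` | `"sd"` | – | "median ± SEM" literally (sd/√n); `"bootstrap"` gives the SE of the median |

## What the acceptance surface does and does not establish

The experimental condition medians of any filmed cohort depend on the
animals and are not reproducible from synthetic data; they are not asserted
anywhere. What is asserted: the analytic anchors of the ε formula (0, 2, 1
at its three reference points), the stimulus mean-speed identities
(240/720°/s), the ideal-compensation identity (gain 1, phase 180° by both
estimators), parameter recovery over a generative grid (median gain within
±0.02, circular-median phase within ±3°), cross-estimator agreement (≤5° on
≥95% of default-noise seeds), coherence bounds and monotonicity in noise,
null calibration of the non-parametric tests at α = 0.05, and the exact
signed-rank floor p at n = 8.

## Known limitations

* The feedback-loop simulator is a first-order extrapolation for testing
  the estimators, not a biomechanical neck model.
* Marker digitization from video is upstream of this package; only
  marker-coordinate tables are consumed.
* No frequency-sweep system identification: metrics are single-frequency
  per trial, as in the assay.
* `stimulus_spec()` requires an integer number of samples per cycle, which
  both assay frequencies satisfy; arbitrary (f, sample rate) pairs that
  violate it are rejected rather than approximated.
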