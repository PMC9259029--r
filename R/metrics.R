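#' Polar response point
#'
#' The unit of all polar plots and of the compensation error: a response is
#' summarized as a point with radius `r` (gain) and angle `theta` (phase,
#' degrees). Perfect head stabilization sits at (1, 180); no response at all
#' has r = 0.
#'
#' @param r Gain (>= 0).
#' @param theta Phase in degrees, stored modulo 360.
#' @return Object of class `"polar_response"`.
#' @export
polar_response <- function(r, theta) {
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop("`r` must be a single number >= 0", call. = FALSE)
  structure(list(r = r, theta = theta %% 360), class = "polar_response")
}

#' Distance between two polar points
#'
#' Law of cosines in the polar plane:
#' `d = sqrt(r1^2 + r2^2 - 2 r1 r2 cos(theta1 - theta2))`.
#'
#' @param p1,p2 [polar_response()] points.
#' @return Non-negative distance.
#' @export
polar_distance <- function(p1, p2) {
  stopifnot(inherits(p1, "polar_response"), inherits(p2, "polar_response"))
  d2 <- p1$r^2 + p2$r^2 -
    2 * p1$r * p2$r * cos((p1$theta - p2$theta) * pi / 180)
  sqrt(max(d2, 0))
}

#' Compensation error of a response
#'
#' Distance in the polar (gain, phase) plane between the response point and
#' the perfect-stabilization point (1, 180):
#' `epsilon = sqrt(1 + r^2 + 2 r cos(theta))`. It is 0 for perfect
#' compensation (1, 180), 2 for a fully in-phase unit response (1, 0), and 1
#' when there is no head movement relative to the thorax (r = 0); for gain
#' <= 1 it ranges over \[0, 2\].
#'
#' @param p A [polar_response()], or a numeric gain if `theta` is given.
#' @param theta Phase in degrees (used when `p` is numeric).
#' @return The compensation error.
#' @export
compensation_error <- function(p, theta = NULL) {
  if (is.numeric(p) && !is.null(theta)) p <- polar_response(p, theta)
  stopifnot(inherits(p, "polar_response"))
  sqrt(max(1 + p$r^2 + 2 * p$r * cos(p$theta * pi / 180), 0))
}

#' Fourier amplitude of a series at a stimulus frequency
#'
#' Single-sided DFT amplitude (half-range, in the series' units) of the
#' component at `f`, computed at the exact DFT bin of the window -- the window
#' must span a whole number of cycles of `f` (as produced by
#' [exclude_ramps()]) so the estimate is leakage-free; no interpolation
#' between bins is performed.
#'
#' @param series Angle series (full trial length).
#' @param f Frequency in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param window An [analysis_window()]; `NULL` uses the whole series.
#' @return Amplitude in the series' units.
#' @export
amplitude_at <- function(series, f, sample_rate, window = NULL) {
  seg <- if (is.null(window)) series else series[window_indices(window)]
  n <- length(seg)
  k <- f * n / sample_rate
  if (k < 1)
    stop("window shorter than one cycle of `f`", call. = FALSE)
  if (abs(k - round(k)) > 1e-6)
    stop("`f` is not on the window's frequency grid (non-integer cycles)",
         call. = FALSE)
  2 * Mod(stats::fft(seg)[round(k) + 1L]) / n
}

#' Gain of a response (Fourier amplitude ratio)
#'
#' Gain = amplitude of the head-minus-thorax response at the stimulus
#' frequency divided by the amplitude of the thorax stimulus at that
#' frequency, both measured over the same whole-cycle window.
#'
#' @param stim,resp Stimulus and response angle series.
#' @param f Stimulus frequency in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param window An [analysis_window()].
#' @param stim_floor Minimum admissible stimulus amplitude (degrees); below it
#'   there is no stimulus to reference and an error is raised.
#' @return Gain (dimensionless, >= 0).
#' @export
compute_gain <- function(stim, resp, f, sample_rate, window = NULL,
                         stim_floor = 1e-6) {
  a_stim <- amplitude_at(stim, f, sample_rate, window)
  if (a_stim < stim_floor)
    stop("stimulus amplitude at `f` is below the floor (no stimulus)",
         call. = FALSE)
  amplitude_at(resp, f, sample_rate, window) / a_stim
}

# Circular cross-correlation c(k) = sum_i stim[i] * resp[i + k] over the
# window, via the FFT; exact for whole-cycle windows.
circular_xcorr <- function(stim, resp) {
  n <- length(stim)
  s <- stats::fft(stim)
  r <- stats::fft(resp)
  Re(stats::fft(Conj(s) * r, inverse = TRUE)) / n
}

#' Phase from the cross-correlation lag
#'
#' Finds the lag (in samples) maximizing the stimulus-response
#' cross-correlation, searching only lags spanning one stimulus period (the
#' correlation of sinusoids is periodic, so a wider search is ill-posed) with
#' ties broken toward the smallest absolute lag, and converts it to a phase
#' `360 * f * dt` in degrees, mapped to \[0, 360). The convention is
#' delay-positive: a response lagging the stimulus by a quarter period scores
#' 90, an anti-phase response 180. Series are de-meaned over the window; the
#' correlation is circular over the whole-cycle window, which keeps the lag
#' estimate free of end effects.
#'
#' @inheritParams compute_gain
#' @return Phase in degrees in \[0, 360). Lag resolution is
#'   `360 * f / sample_rate` degrees.
#' @export
phase_xcorr <- function(stim, resp, f, sample_rate, window = NULL) {
  idx <- if (is.null(window)) seq_along(stim) else window_indices(window)
  s <- stim[idx]; r <- resp[idx]
  s <- s - mean(s); r <- r - mean(r)
  if (stats::sd(s) == 0 || stats::sd(r) == 0)
    stop_flat_series()
  n <- length(s)
  cc <- circular_xcorr(s, r)
  lags <- c(0:(n - 1))
  lags[lags > n / 2] <- lags[lags > n / 2] - n
  period <- as.integer(round(sample_rate / f))
  keep <- abs(lags) <= period
  cand_lags <- lags[keep]
  cand_cc <- cc[keep]
  ord <- order(abs(cand_lags), cand_lags)  # smallest |lag| wins ties
  best <- ord[which.max(cand_cc[ord])]
  (360 * f * cand_lags[best] / sample_rate) %% 360
}

#' Phase from the FFT at the stimulus frequency
#'
#' Phase difference between stimulus and response taken from the complex DFT
#' at the exact stimulus bin, `Arg S(f) - Arg R(f)` in degrees mapped to
#' \[0, 360), sharing the delay-positive convention of [phase_xcorr()] (a
#' response delayed by a quarter period scores exactly 90, with no lag-grid
#' quantization).
#'
#' @inheritParams compute_gain
#' @return Phase in degrees in \[0, 360).
#' @export
phase_fft <- function(stim, resp, f, sample_rate, window = NULL) {
  idx <- if (is.null(window)) seq_along(stim) else window_indices(window)
  s <- stim[idx]; r <- resp[idx]
  if (stats::sd(s) == 0 || stats::sd(r) == 0)
    stop_flat_series()
  n <- length(s)
  k <- f * n / sample_rate
  if (abs(k - round(k)) > 1e-6)
    stop("`f` is not on the window's frequency grid", call. = FALSE)
  bin <- round(k) + 1L
  S <- stats::fft(s - mean(s))[bin]
  R <- stats::fft(r - mean(r))[bin]
  ((Arg(S) - Arg(R)) * 180 / pi) %% 360
}

stop_flat_series <- function() {
  cnd <- structure(
    class = c("gazestab_flat_series", "error", "condition"),
    list(message = "flat (zero-variance) series: phase is undefined",
         call = sys.call(-1)))
  stop(cnd)
}

#' Spectral-averaging configuration for coherence
#'
#' Welch parameters for [msc_coherence()]: Hann-tapered segments of
#' `segment_cycles` stimulus cycles with fractional `overlap`. The default of
#' one cycle per segment maximizes the number of averaging segments on the
#' short assay records (13 segments on a 7-cycle window), keeping the
#' null-coherence bias (roughly one over the effective segment count) near
#' 0.1; two-cycle segments leave only 6 segments and a null bias of ~0.2,
#' which would make a noise-only response indistinguishable from a weakly
#' coherent one.
#'
#' @param segment_cycles Segment length in stimulus cycles.
#' @param overlap Fractional overlap between segments in \[0, 1).
#' @return Object of class `"psd_config"`.
#' @export
psd_config <- function(segment_cycles = 1, overlap = 0.5) {
  if (segment_cycles < 1) stop("`segment_cycles` must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  structure(list(segment_cycles = segment_cycles, overlap = overlap),
            class = "psd_config")
}

#' Magnitude-squared coherence at the stimulus frequency
#'
#' Welch-averaged magnitude-squared coherence
#' `Cxy(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))` between stimulus and response,
#' evaluated at the segment-DFT bin nearest `f`. Values lie in \[0, 1\]; 1
#' means the two series are linearly well matched at that frequency. With a
#' single segment the estimate is identically 1, so at least two averaging
#' segments are required (shorten `segment_cycles` or lengthen the window).
#'
#' @inheritParams compute_gain
#' @param config A [psd_config()].
#' @return Coherence in \[0, 1\].
#' @export
msc_coherence <- function(stim, resp, f, sample_rate, window = NULL,
                          config = psd_config()) {
  stopifnot(inherits(config, "psd_config"))
  idx <- if (is.null(window)) seq_along(stim) else window_indices(window)
  s <- stim[idx]; r <- resp[idx]
  nseg <- as.integer(round(config$segment_cycles * sample_rate / f))
  step <- max(1L, as.integer(floor(nseg * (1 - config$overlap))))
  starts <- seq.int(1L, length(s) - nseg + 1L, by = step)
  if (length(s) < nseg || length(starts) < 2L)
    stop(paste("coherence needs >= 2 averaging segments;",
               "reduce `segment_cycles` in psd_config()"), call. = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1L) / nseg))  # periodic Hann
  bin <- as.integer(round(f * nseg / sample_rate)) + 1L
  pxx <- 0; pyy <- 0; pxy <- 0 + 0i
  for (st in starts) {
    xs <- s[st:(st + nseg - 1L)]; ys <- r[st:(st + nseg - 1L)]
    X <- stats::fft(w * (xs - mean(xs)))[bin]
    Y <- stats::fft(w * (ys - mean(ys)))[bin]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + Conj(X) * Y
  }
  if (pxx == 0 || pyy == 0) return(0)
  min(1, Mod(pxy)^2 / (pxx * pyy))
}

#' Analysis configuration
#'
#' Tunables of the per-trial pipeline: the zero-phase Butterworth
#' pre-filter (designed order 7, 25 Hz cutoff, suppressing the ~30 Hz
#' wingbeat tone), the phase estimator feeding the compensation error
#' (`"xcorr"`, the primary method, or `"fft"`, the cross-check), the gain
#' floor below which a trial is treated as having no interpretable phase, and
#' the coherence averaging settings.
#'
#' @param apply_filter Low-pass filter both series before analysis?
#' @param filter_order Designed Butterworth order.
#' @param filter_cutoff Cutoff frequency in Hz.
#' @param phase_method `"xcorr"` or `"fft"`: which phase enters the
#'   compensation error.
#' @param min_gain_for_phase Gain below which the phase is flagged undefined.
#' @param stim_floor Minimum stimulus amplitude at `f` in degrees.
#' @param psd A [psd_config()].
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(apply_filter = TRUE, filter_order = 7,
                            filter_cutoff = 25,
                            phase_method = c("xcorr", "fft"),
                            min_gain_for_phase = 0.05,
                            stim_floor = 1e-6,
                            psd = psd_config()) {
  structure(
    list(apply_filter = isTRUE(apply_filter), filter_order = filter_order,
         filter_cutoff = filter_cutoff,
         phase_method = match.arg(phase_method),
         min_gain_for_phase = min_gain_for_phase,
         stim_floor = stim_floor, psd = psd),
    class = "analysis_config"
  )
}

#' Analyze one trial
#'
#' Runs the full per-trial quantification: zero-phase low-pass filtering of
#' both angle series, ramp exclusion and whole-cycle trimming, Fourier
#' amplitudes and gain, phase by both estimators, compensation error (from the
#' configured phase method), and magnitude-squared coherence. When the gain
#' falls below `config$min_gain_for_phase` the response is treated as absent:
#' both phases are reported `NA` with flag `"phase_undefined"` (the raw phase
#' estimate still feeds the compensation error, which is ~1 regardless of
#' phase at near-zero gain). Deterministic for a fixed input.
#'
#' @param x A [trial()].
#' @param spec The trial's [stimulus_spec()].
#' @param config An [analysis_config()].
#' @return Object of class `"trial_metrics"`: gain, `phase_xcorr`,
#'   `phase_fft`, `epsilon`, `coherence`, `stim_amplitude`, `resp_amplitude`,
#'   `flags`, plus the trial metadata.
#' @export
analyze_trial <- function(x, spec, config = analysis_config()) {
  stopifnot(inherits(x, "trial"), inherits(spec, "stimulus_spec"),
            inherits(config, "analysis_config"))
  sr <- spec$sample_rate
  f <- spec$frequency
  stim <- x$theta_thorax
  resp <- x$theta_head_thorax
  if (config$apply_filter) {
    stim <- lowpass_filter(stim, sr, config$filter_order, config$filter_cutoff)
    resp <- lowpass_filter(resp, sr, config$filter_order, config$filter_cutoff)
  }
  win <- exclude_ramps(length(stim), spec)
  a_stim <- amplitude_at(stim, f, sr, win)
  if (a_stim < config$stim_floor)
    stop("stimulus amplitude at `f` is below the floor (no stimulus)",
         call. = FALSE)
  a_resp <- amplitude_at(resp, f, sr, win)
  gain <- a_resp / a_stim
  flags <- character()
  ph_x <- tryCatch(phase_xcorr(stim, resp, f, sr, win),
                   gazestab_flat_series = function(e) NA_real_)
  ph_f <- tryCatch(phase_fft(stim, resp, f, sr, win),
                   gazestab_flat_series = function(e) NA_real_)
  raw_phase <- if (config$phase_method == "xcorr") ph_x else ph_f
  if (is.na(raw_phase)) flags <- c(flags, "phase_undefined")
  eps <- if (is.na(raw_phase)) {
    # flat response: no head movement relative to thorax
    compensation_error(polar_response(gain, 0))
  } else {
    compensation_error(polar_response(gain, raw_phase))
  }
  if (!is.na(raw_phase) && gain < config$min_gain_for_phase) {
    flags <- c(flags, "phase_undefined")
    ph_x <- NA_real_
    ph_f <- NA_real_
  }
  coh <- msc_coherence(stim, resp, f, sr, win, config$psd)
  structure(
    list(gain = gain, phase_xcorr = ph_x, phase_fft = ph_f,
         epsilon = eps, coherence = coh, flags = unique(flags),
         stim_amplitude = a_stim, resp_amplitude = a_resp,
         meta = x$meta),
    class = "trial_metrics"
  )
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf(
    "<trial_metrics> gain=%.3f phase_xcorr=%s phase_fft=%s eps=%.3f coh=%.3f%s\n",
    x$gain,
    ifelse(is.na(x$phase_xcorr), "NA", sprintf("%.1f", x$phase_xcorr)),
    ifelse(is.na(x$phase_fft), "NA", sprintf("%.1f", x$phase_fft)),
    x$epsilon, x$coherence,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' @export
as.data.frame.trial_metrics <- function(x, ...) {
  meta <- x$meta
  pick <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA else v
  }
  data.frame(
    trial_id = as.character(pick("trial_id")),
    animal_id = as.character(pick("animal_id")),
    treatment = as.character(pick("treatment")),
    light = as.character(pick("light")),
    frequency = as.numeric(pick("frequency")),
    gain = x$gain,
    phase_xcorr_deg = x$phase_xcorr,
    phase_fft_deg = x$phase_fft,
    epsilon = x$epsilon,
    coherence = x$coherence,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
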