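#' Stimulus specification for a sinusoidal roll trial
#'
#' Describes the imposed body-roll stimulus: a sinusoid of half-range
#' `amplitude` degrees at `frequency` Hz, lasting `n_cycles` cycles, sampled at
#' `sample_rate` Hz. When `ramp_endpoints` is `TRUE` the first and last quarter
#' cycle are replaced by linear ramps (0 to +A, and -A back to 0) so the motor
#' never has to produce the peak sinusoidal acceleration at onset/offset; the
#' matching response intervals are excluded from analysis by
#' [exclude_ramps()].
#'
#' The defaults mirror the tethered-moth roll assay: +/-30 deg at 2 or 6 Hz,
#' 8 cycles, filmed at 1200 frames/s. `sample_rate / frequency` must be a whole
#' number of samples per cycle (it is for both assay frequencies) so that the
#' whole-cycle analysis window puts `frequency` exactly on the DFT grid.
#'
#' @param frequency Stimulus frequency in Hz (> 0).
#' @param amplitude Half-range amplitude in degrees (> 0); peak-to-peak is
#'   `2 * amplitude`.
#' @param n_cycles Number of stimulus cycles (integer >= 1).
#' @param sample_rate Sampling rate in Hz; must exceed `2 * frequency`.
#' @param ramp_endpoints Replace the first/last quarter cycle with linear
#'   ramps?
#' @return An object of class `"stimulus_spec"`.
#' @examples
#' spec <- stimulus_spec(frequency = 2)
#' theta <- generate_stimulus(spec)
#' range(theta)
#' @export
stimulus_spec <- function(frequency, amplitude = 30, n_cycles = 8,
                          sample_rate = 1200, ramp_endpoints = TRUE) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("`frequency` must be a single positive number", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude <= 0)
    stop("`amplitude` must be a single positive number", call. = FALSE)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles))
    stop("`n_cycles` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 2 * frequency)
    stop("`sample_rate` must exceed 2 * frequency (aliasing)", call. = FALSE)
  spc <- sample_rate / frequency
  if (abs(spc - round(spc)) > 1e-8)
    stop("`sample_rate / frequency` must be an integer number of samples per cycle",
         call. = FALSE)
  structure(
    list(frequency = frequency, amplitude = amplitude,
         n_cycles = as.integer(n_cycles), sample_rate = sample_rate,
         ramp_endpoints = isTRUE(ramp_endpoints)),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %.3g Hz, +/-%.3g deg, %d cycles @ %.5g Hz%s\n",
    x$frequency, x$amplitude, x$n_cycles, x$sample_rate,
    if (x$ramp_endpoints) ", quarter-cycle ramp endpoints" else ""))
  invisible(x)
}

#' Generate the thorax-roll stimulus waveform
#'
#' Samples `A * sin(2 pi f t)` on the trial time grid. With
#' `spec$ramp_endpoints`, the first quarter cycle is replaced by the line
#' `4 A f * t` (0 up to +A) and the last quarter cycle by `-4 A f * (T - t)`
#' (-A back up to 0), each of duration `1/(4 f)` s; position is continuous at
#' both junctions and the mean absolute angular speed over a ramp equals the
#' sinusoid's cycle average `4 A f` (240 deg/s for +/-30 deg at 2 Hz, 720 deg/s
#' at 6 Hz).
#'
#' @param spec A [stimulus_spec()].
#' @return Numeric vector of thorax angles in degrees, one per sample
#'   (`n_cycles * sample_rate / frequency` samples starting at t = 0).
#' @export
generate_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  f <- spec$frequency
  n <- as.integer(round(spec$n_cycles * spec$sample_rate / f))
  t <- (seq_len(n) - 1) / spec$sample_rate
  theta <- spec$amplitude * sin(2 * pi * f * t)
  if (spec$ramp_endpoints) {
    total <- spec$n_cycles / f
    q <- 1 / (4 * f)
    slope <- 4 * spec$amplitude * f
    head_idx <- t < q
    tail_idx <- t > total - q
    theta[head_idx] <- slope * t[head_idx]
    theta[tail_idx] <- -slope * (total - t[tail_idx])
  }
  theta
}

#' Time grid of a stimulus specification
#' @param spec A [stimulus_spec()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
stimulus_time <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- as.integer(round(spec$n_cycles * spec$sample_rate / spec$frequency))
  (seq_len(n) - 1) / spec$sample_rate
}

#' Mean absolute angular speed of a sampled angle series
#'
#' Discrete estimate `mean(|diff(theta)|) * sample_rate`, the quantity quoted
#' as the stimulus "mean angular speed" (4 A f for a sinusoid or its
#' quarter-cycle ramp replacement).
#'
#' @param theta Angle series in degrees.
#' @param sample_rate Sampling rate in Hz.
#' @return Mean absolute angular speed in degrees per second.
#' @export
mean_angular_speed <- function(theta, sample_rate) {
  if (length(theta) < 2L) stop("need at least two samples", call. = FALSE)
  mean(abs(diff(theta))) * sample_rate
}
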