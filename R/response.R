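# Seeded evaluation that does not disturb the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generative model of a compensatory head-roll response
#'
#' Describes the synthetic head response to a sinusoidal roll stimulus: a
#' sinusoid at the stimulus frequency with target `gain` (response amplitude /
#' stimulus amplitude) and `phase` (degrees of response lag; 180 means
#' anti-phase, i.e. ideal compensation), contaminated by a wingbeat-frequency
#' tone (~30 Hz in this moth), a small low-frequency head wobble (~12 Hz), and
#' Gaussian broadband noise. The contaminant phases are drawn uniformly per
#' trial from the seeded generator, so a given `seed` reproduces the trial
#' bit-for-bit.
#'
#' Default noise levels are the package's stated synthetic world: 2 deg of
#' wingbeat tone, 0.5 deg of wobble, 0.5 deg white noise.
#'
#' @param gain Target gain (>= 0).
#' @param phase Target phase in degrees, stored modulo 360.
#' @param wingbeat_freq Wingbeat contamination frequency, Hz.
#' @param wingbeat_amp Wingbeat tone amplitude, degrees (>= 0).
#' @param wobble_freq Head-wobble frequency, Hz.
#' @param wobble_amp Head-wobble amplitude, degrees (>= 0).
#' @param noise_sd Standard deviation of additive white noise, degrees (>= 0).
#' @param seed Integer seed for the trial's random components.
#' @return An object of class `"response_model"`.
#' @export
response_model <- function(gain = 0.6, phase = 177.6,
                           wingbeat_freq = 30, wingbeat_amp = 2,
                           wobble_freq = 12, wobble_amp = 0.5,
                           noise_sd = 0.5, seed = 1L) {
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0)
    stop("`gain` must be a single number >= 0", call. = FALSE)
  amps <- c(wingbeat_amp = wingbeat_amp, wobble_amp = wobble_amp,
            noise_sd = noise_sd)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("noise amplitudes must be finite and >= 0", call. = FALSE)
  if (wingbeat_freq <= 0 || wobble_freq <= 0)
    stop("contaminant frequencies must be positive", call. = FALSE)
  structure(
    list(gain = gain, phase = phase %% 360,
         wingbeat_freq = wingbeat_freq, wingbeat_amp = wingbeat_amp,
         wobble_freq = wobble_freq, wobble_amp = wobble_amp,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "response_model"
  )
}

#' Generate a synthetic trial from a response model
#'
#' The head-minus-thorax series is
#' `gain * A * sin(2 pi f t - phase)` plus the seeded wingbeat tone, wobble
#' tone, and white noise; `phase` is therefore the phase *lag* recovered by the
#' package's estimators (a response delayed by `1/(4 f)` has phase 90, and
#' `phase = 180` with zero noise gives exactly `-theta_thorax` over the
#' non-ramp segment). The thorax channel is the supplied stimulus waveform.
#'
#' @param stimulus Stimulus waveform from [generate_stimulus()].
#' @param model A [response_model()].
#' @param spec The [stimulus_spec()] that produced `stimulus`.
#' @param meta Extra metadata stored on the trial.
#' @return A [trial()]; its metadata records the generative parameters.
#' @export
generate_response <- function(stimulus, model, spec, meta = list()) {
  stopifnot(inherits(model, "response_model"), inherits(spec, "stimulus_spec"))
  t <- stimulus_time(spec)
  if (length(stimulus) != length(t))
    stop("`stimulus` length does not match `spec`", call. = FALSE)
  f <- spec$frequency
  phi <- model$phase * pi / 180
  base <- model$gain * spec$amplitude * sin(2 * pi * f * t - phi)
  contam <- with_local_seed(model$seed, {
    wb_phase <- stats::runif(1, 0, 2 * pi)
    wob_phase <- stats::runif(1, 0, 2 * pi)
    noise <- if (model$noise_sd > 0) stats::rnorm(length(t), 0, model$noise_sd)
             else numeric(length(t))
    model$wingbeat_amp * sin(2 * pi * model$wingbeat_freq * t + wb_phase) +
      model$wobble_amp * sin(2 * pi * model$wobble_freq * t + wob_phase) +
      noise
  })
  meta <- utils::modifyList(
    list(frequency = f, amplitude = spec$amplitude,
         gain_true = model$gain, phase_true = model$phase,
         seed = model$seed),
    meta)
  trial(t, stimulus, base + contam, meta = meta)
}

#' Delayed multisensory feedback-loop model
#'
#' A declared extrapolation of the proposed control structure: two sensory
#' channels (visual, antennal-mechanosensory) each observe the imposed thorax
#' roll with their own gain and pure time delay, their sum drives a
#' compensatory (sign-inverted) head command, and the neck plant is a
#' first-order low-pass. No functional forms for the channels are established
#' for this system; `channel_input` selects whether the channels sense thorax
#' angle or angular velocity (default angle).
#'
#' @param visual_gain,mech_gain Channel gains (>= 0).
#' @param visual_delay,mech_delay Channel delays in seconds (>= 0), rounded to
#'   whole samples at simulation time.
#' @param neck_time_constant First-order neck time constant in seconds
#'   (0 = instantaneous plant).
#' @param channel_input `"angle"` or `"velocity"`.
#' @return An object of class `"feedback_model"`.
#' @export
feedback_model <- function(visual_gain = 0.6, visual_delay = 0.05,
                           mech_gain = 0.3, mech_delay = 0.01,
                           neck_time_constant = 0.02,
                           channel_input = c("angle", "velocity")) {
  gains <- c(visual_gain, mech_gain)
  delays <- c(visual_delay, mech_delay)
  if (any(gains < 0)) stop("gains must be >= 0", call. = FALSE)
  if (any(delays < 0)) stop("delays must be >= 0", call. = FALSE)
  if (neck_time_constant < 0)
    stop("`neck_time_constant` must be >= 0", call. = FALSE)
  structure(
    list(visual_gain = visual_gain, visual_delay = visual_delay,
         mech_gain = mech_gain, mech_delay = mech_delay,
         neck_time_constant = neck_time_constant,
         channel_input = match.arg(channel_input)),
    class = "feedback_model"
  )
}

delay_samples <- function(x, d) {
  if (d == 0) return(x)
  c(rep(0, d), x[seq_len(length(x) - d)])
}

#' Simulate the delayed feedback loop on a stimulus
#'
#' Head command `u(t) = -(gv * s(t - tau_v) + gm * s(t - tau_m))` with delays
#' rounded to the nearest sample (the record is zero before t = 0), passed
#' through the first-order neck filter integrated with the exact exponential
#' update `y[i] = a y[i-1] + (1 - a) u[i]`, `a = exp(-dt / tau_n)`. The
#' discrete transfer function at frequency f is therefore exactly
#' `-(gv z^-dv + gm z^-dm) (1 - a) / (1 - a z^-1)` with `z = exp(2 pi i f dt)`,
#' which tests use as a closed-form oracle.
#'
#' @param stimulus Stimulus waveform from [generate_stimulus()].
#' @param fb A [feedback_model()].
#' @param spec The [stimulus_spec()] that produced `stimulus`.
#' @param meta Extra metadata stored on the trial.
#' @return A [trial()].
#' @export
simulate_feedback_loop <- function(stimulus, fb, spec, meta = list()) {
  stopifnot(inherits(fb, "feedback_model"), inherits(spec, "stimulus_spec"))
  t <- stimulus_time(spec)
  if (length(stimulus) != length(t))
    stop("`stimulus` length does not match `spec`", call. = FALSE)
  sr <- spec$sample_rate
  dv <- as.integer(round(fb$visual_delay * sr))
  dm <- as.integer(round(fb$mech_delay * sr))
  if (max(dv, dm) >= length(stimulus))
    stop("delay longer than the record", call. = FALSE)
  s <- if (fb$channel_input == "velocity")
    c(0, diff(stimulus)) * sr else stimulus
  u <- -(fb$visual_gain * delay_samples(s, dv) +
           fb$mech_gain * delay_samples(s, dm))
  y <- if (fb$neck_time_constant > 0) {
    a <- exp(-1 / (sr * fb$neck_time_constant))
    as.numeric(stats::filter((1 - a) * u, a, method = "recursive"))
  } else u
  meta <- utils::modifyList(
    list(frequency = spec$frequency, amplitude = spec$amplitude,
         model = "feedback_loop"),
    meta)
  trial(t, stimulus, y, meta = meta)
}

#' Closed-form frequency response of the feedback-loop simulator
#'
#' Evaluates the exact discrete transfer function of
#' [simulate_feedback_loop()] (angle input) at a frequency, returning the gain
#' and delay-positive phase the metrics pipeline should recover in steady
#' state.
#'
#' @param fb A [feedback_model()].
#' @param frequency Frequency in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @return List with `gain` and `phase` (degrees in \[0, 360)).
#' @export
feedback_frequency_response <- function(fb, frequency, sample_rate) {
  stopifnot(inherits(fb, "feedback_model"))
  z <- exp(2i * pi * frequency / sample_rate)
  dv <- round(fb$visual_delay * sample_rate)
  dm <- round(fb$mech_delay * sample_rate)
  G <- -(fb$visual_gain * z^(-dv) + fb$mech_gain * z^(-dm))
  if (fb$neck_time_constant > 0) {
    a <- exp(-1 / (sample_rate * fb$neck_time_constant))
    G <- G * (1 - a) / (1 - a / z)
  }
  list(gain = Mod(G), phase = (-Arg(G) * 180 / pi) %% 360)
}
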