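spec2 <- stimulus_spec(2)
win2 <- exclude_ramps(4800, spec2)
t2 <- stimulus_time(spec2)

test_that("amplitude_at recovers pure-tone amplitudes on whole cycles", {
  x <- 30 * sin(2 * pi * 2 * t2)
  expect_equal(amplitude_at(x, 2, 1200, win2), 30, tolerance = 1e-10)
  # orthogonality: an added 12 Hz tone does not perturb the 2 Hz bin
  y <- x + 5 * sin(2 * pi * 12 * t2 + 0.7)
  expect_equal(amplitude_at(y, 2, 1200, win2), 30, tolerance = 1e-10)
  expect_equal(amplitude_at(y, 12, 1200, win2), 5, tolerance = 1e-10)
  # white noise leaves only the noise floor at the stimulus bin
  set.seed(3)
  floor_amp <- replicate(30, amplitude_at(rnorm(4800), 2, 1200, win2))
  expect_lt(median(floor_amp), 0.1)
  # off-grid frequencies and too-short windows are rejected
  expect_error(amplitude_at(x, 2.3, 1200, win2), "frequency grid")
  expect_error(amplitude_at(x[1:100], 2, 1200), "one cycle")
})

test_that("gain is the Fourier amplitude ratio", {
  stim <- generate_stimulus(spec2)
  expect_equal(compute_gain(stim, -stim, 2, 1200, win2), 1)
  shifted <- 0.5 * 30 * sin(2 * pi * 2 * t2 + 1.1)
  expect_equal(compute_gain(stim, shifted, 2, 1200, win2), 0.5,
               tolerance = 1e-10)
  set.seed(4)
  expect_lt(compute_gain(stim, rnorm(4800), 2, 1200, win2), 0.05)
  expect_error(compute_gain(numeric(4800), stim, 2, 1200, win2), "floor")
})

test_that("cross-correlation phase handles the canonical cases", {
  stim <- generate_stimulus(spec2)
  expect_equal(phase_xcorr(stim, -stim, 2, 1200, win2), 180)
  expect_equal(phase_xcorr(stim, stim, 2, 1200, win2), 0)
  # constructed quarter-period delay: 90 deg within the lag resolution
  d <- 150L  # 1/(4f) at 1200 Hz
  delayed <- c(rep(0, d), stim[seq_len(4800 - d)])
  ph <- phase_xcorr(stim, delayed, 2, 1200, win2)
  expect_lt(abs(circ_signed_diff(ph, 90)), 360 * 2 / 1200 + 1e-9)
  expect_error(phase_xcorr(stim, numeric(4800), 2, 1200, win2),
               class = "gazestab_flat_series")
})

test_that("FFT phase is exact and agrees with the lag estimator", {
  stim <- generate_stimulus(spec2)
  expect_equal(phase_fft(stim, -stim, 2, 1200, win2), 180, tolerance = 1e-9)
  d <- 150L
  delayed <- c(rep(0, d), stim[seq_len(4800 - d)])
  expect_equal(phase_fft(stim, delayed, 2, 1200, win2), 90, tolerance = 1e-6)
  # noisy synthetic trial: the two estimators stay within 5 degrees
  tr <- noisy_trial(0.6, 177.6, seed = 21)
  m <- analyze_trial(tr, spec2)
  expect_lt(abs(circ_signed_diff(m$phase_fft, m$phase_xcorr)), 5)
  expect_error(phase_fft(stim, numeric(4800), 2, 1200, win2),
               class = "gazestab_flat_series")
})

test_that("polar distance follows the law of cosines", {
  p <- polar_response(0.8, 123)
  expect_equal(polar_distance(p, p), 0)
  expect_equal(polar_distance(polar_response(1, 0), polar_response(1, 180)), 2)
  expect_equal(polar_distance(polar_response(1, 180), polar_response(0.5, 90)),
               sqrt(1.25))
  q <- polar_response(0.3, 301)
  expect_equal(polar_distance(p, q), polar_distance(q, p))
})

test_that("compensation error anchors and identity with polar distance", {
  expect_equal(compensation_error(polar_response(1, 180)), 0)
  expect_equal(compensation_error(polar_response(1, 0)), 2)
  expect_equal(compensation_error(polar_response(0, 0)), 1)
  ideal <- polar_response(1, 180)
  set.seed(8)
  for (i in 1:50) {
    p <- polar_response(runif(1, 0, 1.5), runif(1, 0, 360))
    expect_equal(compensation_error(p), polar_distance(p, ideal),
                 tolerance = 1e-12)
    if (p$r <= 1) {
      expect_gte(compensation_error(p), 0)
      expect_lte(compensation_error(p), 2)
    }
  }
})

test_that("coherence is 1 for a noise-free linear response and low for noise", {
  stim <- generate_stimulus(spec2)
  expect_gte(msc_coherence(stim, -0.6 * stim + 3, 2, 1200, win2), 0.999)
  set.seed(5)
  nulls <- replicate(20, msc_coherence(stim, rnorm(4800), 2, 1200, win2))
  expect_lt(mean(nulls), 0.35)
  # single-segment estimates are degenerate and refused
  expect_error(
    msc_coherence(stim, -stim, 2, 1200, win2,
                  psd_config(segment_cycles = 7)),
    "2 averaging segments")
})

test_that("coherence is non-increasing along a noise ladder", {
  spec <- spec2
  stim <- generate_stimulus(spec)
  ladder <- c(0, 0.5, 2, 8)
  seeds <- 1:8
  mean_coh <- vapply(ladder, function(ns) {
    mean(vapply(seeds, function(s) {
      model <- response_model(gain = 0.6, phase = 177.6, wingbeat_amp = 2,
                              wobble_amp = 0.5, noise_sd = ns, seed = s)
      tr <- generate_response(stim, model, spec)
      win <- exclude_ramps(tr, spec)
      msc_coherence(tr$theta_thorax, tr$theta_head_thorax, 2, 1200, win)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_coh) <= 1e-6))
})

test_that("analyze_trial composes the stages coherently", {
  # ideal compensation
  stim <- generate_stimulus(spec2)
  ideal <- trial(t2, stim, -stim)
  m <- analyze_trial(ideal, spec2)
  expect_equal(m$gain, 1, tolerance = 1e-9)
  expect_equal(m$epsilon, 0, tolerance = 1e-6)
  expect_gte(m$coherence, 0.99)
  # noise-free generative identity at the stated tolerances
  for (pars in list(c(0.37, 302.4), c(1, 90))) {
    tr <- noise_free_trial(pars[1], pars[2])
    mm <- analyze_trial(tr, spec2)
    expect_equal(mm$gain, pars[1], tolerance = 1e-6)
    expect_lt(abs(circ_signed_diff(mm$phase_xcorr, pars[2])), 0.5)
  }
  # zero response: gain ~ 0, epsilon ~ 1, phase flagged undefined
  zero <- trial(t2, stim, numeric(4800))
  mz <- analyze_trial(zero, spec2)
  expect_equal(mz$gain, 0, tolerance = 1e-9)
  expect_equal(mz$epsilon, 1, tolerance = 1e-6)
  expect_true(is.na(mz$phase_xcorr))
  expect_true("phase_undefined" %in% mz$flags)
  # near-zero-gain noisy trial is flagged too, epsilon still ~ 1
  tnoise <- noisy_trial(0, 0, seed = 13)
  mn <- analyze_trial(tnoise, spec2)
  expect_true("phase_undefined" %in% mn$flags)
  expect_equal(mn$epsilon, 1, tolerance = 0.1)
})

test_that("metrics are invariant to a common scale factor", {
  tr <- noisy_trial(0.6, 177.6, seed = 31)
  m1 <- analyze_trial(tr, spec2)
  tr2 <- trial(tr$time, 3.7 * tr$theta_thorax, 3.7 * tr$theta_head_thorax,
               meta = tr$meta)
  m2 <- analyze_trial(tr2, spec2)
  expect_equal(m2$gain, m1$gain, tolerance = 1e-8)
  expect_equal(m2$phase_xcorr, m1$phase_xcorr)
  expect_equal(m2$phase_fft, m1$phase_fft, tolerance = 1e-8)
  expect_equal(m2$epsilon, m1$epsilon, tolerance = 1e-9)
  expect_equal(m2$coherence, m1$coherence, tolerance = 1e-9)
})

test_that("parameter recovery holds on a reduced generative grid", {
  # the full 4 x 4 x 20-seed grid runs in the acceptance suite; this spot
  # check covers the extremes at a handful of seeds
  spec <- spec2
  stim <- generate_stimulus(spec)
  for (pars in list(c(0.1, 90), c(1.0, 302.4))) {
    rec <- vapply(1:5, function(s) {
      model <- response_model(gain = pars[1], phase = pars[2], seed = 100 + s)
      m <- analyze_trial(generate_response(stim, model, spec), spec)
      c(m$gain, m$phase_xcorr)
    }, numeric(2))
    expect_lt(abs(median(rec[1, ]) - pars[1]), 0.02)
    expect_lt(abs(median(circ_signed_diff(rec[2, ], pars[2]))), 3)
  }
})
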