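test_that("confidence ellipse matches the Gaussian closed form", {
  set.seed(202)
  n <- 20000
  sigma <- 0.15
  xy <- data.frame(x = rnorm(n, 0.5, sigma), y = rnorm(n, 0.2, sigma))
  pts <- data.frame(r = sqrt(xy$x^2 + xy$y^2),
                    theta = atan2(xy$y, xy$x) * 180 / pi)
  ell <- confidence_ellipse(pts)
  expect_equal(unname(ell$center), c(0.5, 0.2), tolerance = 0.01)
  # isotropic cloud: axes ratio -> 1, area -> pi * chi2_0.95(2) * sigma^2
  expect_equal(ell$semi_axes[1] / ell$semi_axes[2], 1, tolerance = 0.05)
  area <- pi * prod(ell$semi_axes)
  expect_equal(area, pi * qchisq(0.95, 2) * sigma^2, tolerance = 0.05)
  # empirical coverage of the 95% ellipse
  m <- colMeans(xy); S <- cov(xy)
  d2 <- stats::mahalanobis(xy, m, S)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)
})

test_that("ellipse orientation is rotation-equivariant", {
  set.seed(17)
  x <- rnorm(200, sd = 0.3); y <- rnorm(200, sd = 0.05)
  beta <- 35
  to_polar <- function(x, y)
    data.frame(r = sqrt(x^2 + y^2), theta = atan2(y, x) * 180 / pi)
  e0 <- confidence_ellipse(to_polar(x + 1, y + 0.5))
  b <- beta * pi / 180
  xr <- cos(b) * (x + 1) - sin(b) * (y + 0.5)
  yr <- sin(b) * (x + 1) + cos(b) * (y + 0.5)
  e1 <- confidence_ellipse(to_polar(xr, yr))
  expect_equal(e1$semi_axes, e0$semi_axes, tolerance = 1e-9)
  dtheta <- (e1$orientation - e0$orientation) %% 180
  expect_equal(min(dtheta, 180 - dtheta), beta, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected", {
  same <- data.frame(r = rep(0.5, 5), theta = rep(90, 5))
  expect_error(confidence_ellipse(same), "degenerate")
  expect_error(confidence_ellipse(data.frame(r = c(1, 2), theta = c(0, 0))),
               "3 points")
  collinear <- data.frame(r = 1:5, theta = rep(0, 5))
  expect_error(confidence_ellipse(collinear), "degenerate")
})

test_that("condition summaries aggregate the paper's way", {
  spec <- default_spec()
  one <- analyze_trial(noisy_trial(0.6, 177.6, seed = 41), spec)
  s1 <- summarize_condition(list(one))
  expect_equal(s1$n, 1)
  expect_equal(s1$median_gain, one$gain)
  expect_equal(s1$sem_epsilon, 0)
  expect_null(s1$ellipse)
  expect_error(summarize_condition(list()), "empty")
  # median of {0.3, 0.4, 0.5} is 0.4; SEM = sd/sqrt(n)
  ms <- lapply(c(0.3, 0.4, 0.5), function(e) {
    m <- one; m$epsilon <- e; m
  })
  s3 <- summarize_condition(ms)
  expect_equal(s3$median_epsilon, 0.4)
  expect_equal(s3$sem_epsilon, sd(c(0.3, 0.4, 0.5)) / sqrt(3))
  # bootstrap SEM alternative is finite, positive, deterministic
  sb <- summarize_condition(ms, sem_method = "bootstrap", boot_seed = 3)
  sb2 <- summarize_condition(ms, sem_method = "bootstrap", boot_seed = 3)
  expect_gt(sb$sem_epsilon, 0)
  expect_equal(sb$sem_epsilon, sb2$sem_epsilon)
})

test_that("a synthetic twilight cohort recovers its generative parameters", {
  spec <- default_spec()
  ms <- lapply(1:8, function(s) analyze_trial(noisy_trial(0.6, 177.6, 500 + s),
                                              spec))
  s <- summarize_condition(ms, labels = list(light = "twilight",
                                             frequency = 2))
  expect_equal(s$n, 8)
  expect_lt(abs(s$median_gain - 0.6), 0.02)
  expect_lt(abs(circ_signed_diff(s$circ_median_phase, 177.6)), 3)
  expect_lt(abs(s$median_epsilon - compensation_error(0.6, 177.6)), 0.05)
  # lag-grid quantization can collapse all xcorr phases onto one value,
  # leaving the polar points exactly collinear; the continuous FFT phase
  # spreads them and supports an ellipse
  sf <- summarize_condition(ms, phase_method = "fft",
                            labels = list(light = "twilight", frequency = 2))
  expect_false(is.null(sf$ellipse))
  expect_equal(sf$ellipse$n, 8)
})

test_that("undefined phases are excluded from phase medians, kept in epsilon", {
  spec <- default_spec()
  good <- analyze_trial(noisy_trial(0.6, 177.6, seed = 61), spec)
  flat <- analyze_trial(trial(stimulus_time(spec), generate_stimulus(spec),
                              numeric(4800)), spec)
  s <- summarize_condition(list(good, flat, good))
  expect_equal(s$n, 3)
  expect_false(is.na(s$circ_median_phase))
  expect_equal(s$median_epsilon,
               median(c(good$epsilon, flat$epsilon, good$epsilon)))
})
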