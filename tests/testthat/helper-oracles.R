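# Independent oracles and small builders shared across test files.

# Signed difference a - b on the circle, in (-180, 180].
circ_signed_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Brute-force exact two-sided p for the paired signed-rank test:
# enumerate all 2^n sign assignments of the tie-free |differences|.
enum_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu)))
}

# Brute-force exact two-sided p for the rank-sum test: enumerate all
# choose(n + m, n) assignments of ranks to the first group.
enum_rank_sum_p <- function(x, y) {
  stopifnot(!any(duplicated(c(x, y))))
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(seq_len(n + m)[combos], nrow = n)) -
    n * (n + 1) / 2
  mu <- n * m / 2
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# Von Mises sampler (Best & Fisher 1979 rejection algorithm); mean direction
# mu in degrees, concentration kappa. Used only as a test-data generator.
rvonmises_deg <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  (mu + out * 180 / pi) %% 360
}

# Seeded standard-normal draws that leave the global RNG stream untouched.
with_seed_rnorm <- function(seed, n) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n)
}

# Builders -------------------------------------------------------------

default_spec <- function(frequency = 2, ...) stimulus_spec(frequency, ...)

# Noise-free trial with exact generative gain/phase on the standard stimulus.
noise_free_trial <- function(gain, phase, spec = default_spec()) {
  model <- response_model(gain = gain, phase = phase,
                          wingbeat_amp = 0, wobble_amp = 0, noise_sd = 0)
  generate_response(generate_stimulus(spec), model, spec)
}

# Default-noise synthetic trial.
noisy_trial <- function(gain, phase, seed, spec = default_spec()) {
  model <- response_model(gain = gain, phase = phase, seed = seed)
  generate_response(generate_stimulus(spec), model, spec)
}

# Marker frame table for a thorax line at angle `at` and head line at `ah`
# (degrees clockwise from vertical, y-up), optionally transformed.
marker_frames <- function(at, ah, scale = 1, rot = 0, shift = c(0, 0)) {
  stopifnot(length(at) == length(ah))
  mk <- function(ang, x0 = 0, y0 = 0) {
    a <- ang * pi / 180
    cbind(x0, y0, x0 + sin(a), y0 + cos(a))
  }
  th <- mk(at); hd <- mk(ah)
  tf <- function(x, y) {
    b <- rot * pi / 180
    list(x = scale * (cos(b) * x - sin(b) * y) + shift[1],
         y = scale * (sin(b) * x + cos(b) * y) + shift[2])
  }
  t1 <- tf(th[, 1], th[, 2]); t2 <- tf(th[, 3], th[, 4])
  h1 <- tf(hd[, 1], hd[, 2]); h2 <- tf(hd[, 3], hd[, 4])
  data.frame(frame = seq_along(at),
             x_t1 = t1$x, y_t1 = t1$y, x_t2 = t2$x, y_t2 = t2$y,
             x_h1 = h1$x, y_h1 = h1$y, x_h2 = h2$x, y_h2 = h2$y)
}
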