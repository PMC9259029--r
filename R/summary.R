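#' Cartesian projection of polar response points
#'
#' Maps (r, theta) points to `(r cos(theta), r sin(theta))`, the plane in
#' which ellipses and point means are computed.
#'
#' @param points List of [polar_response()] points, or a data frame /
#'   matrix-like with columns `r` and `theta` (degrees).
#' @return Two-column matrix with columns `x`, `y`.
#' @export
polar_to_cart <- function(points) {
  if (is.list(points) && length(points) && inherits(points[[1]], "polar_response")) {
    r <- vapply(points, `[[`, numeric(1), "r")
    th <- vapply(points, `[[`, numeric(1), "theta")
  } else {
    points <- as.data.frame(points)
    r <- points$r; th <- points$theta
  }
  th <- th * pi / 180
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Sample confidence ellipse of polar response points
#'
#' Ellipse of the sample mean and covariance of the points' Cartesian
#' projection, scaled by the chi-square(2 df) quantile at the requested
#' coverage -- the ellipse expected to enclose that fraction of points drawn
#' from the fitted Gaussian. Needs at least 3 points that are not collinear
#' (non-degenerate covariance).
#'
#' @param points As in [polar_to_cart()].
#' @param coverage Coverage probability, default 0.95.
#' @return Object of class `"ellipse_params"`: `center` (x, y), `semi_axes`
#'   (major, minor), `orientation` (degrees, counter-clockwise from +x of the
#'   major axis, in \[0, 180)), `coverage`, `n`.
#' @export
confidence_ellipse <- function(points, coverage = 0.95) {
  xy <- polar_to_cart(points)
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 points for an ellipse", call. = FALSE)
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  if (!is.finite(tol) || max(ev$values) <= 0 || min(ev$values) <= tol)
    stop("degenerate point cloud (identical or collinear points)",
         call. = FALSE)
  scale2 <- stats::qchisq(coverage, df = 2)
  axes <- sqrt(ev$values * scale2)
  v1 <- ev$vectors[, 1]
  structure(
    list(center = colMeans(xy), semi_axes = axes,
         orientation = (atan2(v1[2], v1[1]) * 180 / pi) %% 180,
         coverage = coverage, n = n),
    class = "ellipse_params"
  )
}

#' Summarize a condition (treatment x light x frequency cell)
#'
#' Aggregates per-trial metrics into the condition-level summary used for
#' reporting: median gain, circular median phase (undefined phases of
#' near-zero-gain trials are excluded from the phase median but their
#' compensation errors are retained), median compensation error with its
#' spread, and the 95% confidence ellipse of the (gain, phase) points when at
#' least 3 are available. The error spread is reported as "median +/- SEM",
#' i.e. `sd(epsilon)/sqrt(n)` alongside the median; set
#' `sem_method = "bootstrap"` for a bootstrap standard error of the median
#' instead.
#'
#' @param metrics List of [analyze_trial()] results (`trial_metrics`).
#' @param labels Named list of condition labels (light, treatment,
#'   frequency, ...).
#' @param phase_method Which per-trial phase feeds the circular median.
#' @param sem_method `"sd"` (sd/sqrt(n)) or `"bootstrap"` (SE of the median).
#' @param boot_n,boot_seed Bootstrap replicate count and seed.
#' @return Object of class `"condition_summary"`.
#' @export
summarize_condition <- function(metrics, labels = list(),
                                phase_method = c("xcorr", "fft"),
                                sem_method = c("sd", "bootstrap"),
                                boot_n = 2000L, boot_seed = 1L) {
  phase_method <- match.arg(phase_method)
  sem_method <- match.arg(sem_method)
  if (!length(metrics)) stop("empty group", call. = FALSE)
  stopifnot(all(vapply(metrics, inherits, logical(1), "trial_metrics")))
  gains <- vapply(metrics, `[[`, numeric(1), "gain")
  eps <- vapply(metrics, `[[`, numeric(1), "epsilon")
  phases <- vapply(metrics, `[[`, numeric(1),
                   if (phase_method == "xcorr") "phase_xcorr" else "phase_fft")
  n <- length(metrics)
  sem <- if (n == 1L) 0
  else if (sem_method == "sd") stats::sd(eps) / sqrt(n)
  else with_local_seed(boot_seed, {
    stats::sd(vapply(seq_len(boot_n), function(i)
      stats::median(sample(eps, n, replace = TRUE)), numeric(1)))
  })
  ph_med <- if (all(is.na(phases))) NA_real_ else circular_median(phases)
  ok <- !is.na(phases)
  ell <- if (sum(ok) >= 3L)
    tryCatch(confidence_ellipse(
      data.frame(r = gains[ok], theta = phases[ok] %% 360)),
      error = function(e) NULL)
  else NULL
  structure(
    list(n = n, median_gain = stats::median(gains),
         circ_median_phase = ph_med,
         median_epsilon = stats::median(eps), sem_epsilon = sem,
         ellipse = ell, labels = labels),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  lab <- if (length(x$labels))
    paste(names(x$labels), unlist(x$labels), sep = "=", collapse = " ") else ""
  cat(sprintf(
    "<condition_summary> %s n=%d gain=%.2f phase=%s eps=%.2f+/-%.3f\n",
    lab, x$n, x$median_gain,
    ifelse(is.na(x$circ_median_phase), "NA",
           sprintf("%.1f", x$circ_median_phase)),
    x$median_epsilon, x$sem_epsilon))
  invisible(x)
}

#' @export
as.data.frame.condition_summary <- function(x, ...) {
  base <- data.frame(
    n = x$n, median_gain = x$median_gain,
    circ_median_phase_deg = x$circ_median_phase,
    median_epsilon = x$median_epsilon, sem_epsilon = x$sem_epsilon,
    stringsAsFactors = FALSE)
  if (length(x$labels))
    base <- cbind(as.data.frame(x$labels, stringsAsFactors = FALSE), base)
  base
}
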