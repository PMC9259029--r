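# Unwrap a degree series along time (removes +/-180 or +/-360 jumps).
unwrap_deg <- function(theta, jump = 360) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - jump * round(d / jump)
  theta[1L] + c(0, cumsum(d))
}

#' Angles from digitized marker coordinates
#'
#' Converts per-frame marker pairs (two points on the tether/thorax axis, two
#' on the head midline) to signed angles between each line and the image
#' vertical, in degrees, and their difference
#' `theta_head_thorax = theta_head - theta_thorax`. Positive is clockwise from
#' vertical in a y-up frame (equivalently counter-clockwise in raw y-down
#' image coordinates; set `vertical_convention = "y_down"` for those). Angle
#' series are unwrapped along time, so they are continuous across the
#' +/-180 deg wrap; only differences are used downstream, making the
#' convention a recording choice rather than a modelling one.
#'
#' Frames whose marker pair is (numerically) coincident cannot define a line:
#' they are flagged and returned as `NA`. If more than `max_flagged_frac` of
#' frames are flagged the digitization is considered unusable and an error is
#' raised.
#'
#' @param frames Data frame with columns
#'   `x_t1, y_t1, x_t2, y_t2, x_h1, y_h1, x_h2, y_h2` (and optionally
#'   `frame`).
#' @param vertical_convention `"y_up"` (default) or `"y_down"`.
#' @param max_flagged_frac Maximum tolerated fraction of flagged frames.
#' @return List with `theta_thorax`, `theta_head`, `theta_head_thorax`
#'   (degrees, `NA` at flagged frames) and the logical `flagged` vector.
#' @export
angles_from_markers <- function(frames,
                                vertical_convention = c("y_up", "y_down"),
                                max_flagged_frac = 0.05) {
  vertical_convention <- match.arg(vertical_convention)
  need <- c("x_t1", "y_t1", "x_t2", "y_t2", "x_h1", "y_h1", "x_h2", "y_h2")
  if (!all(need %in% names(frames)))
    stop("`frames` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ysign <- if (vertical_convention == "y_up") 1 else -1
  line_angle <- function(x1, y1, x2, y2) {
    dx <- x2 - x1
    dy <- ysign * (y2 - y1)
    len <- sqrt(dx^2 + dy^2)
    ang <- atan2(dx, dy) * 180 / pi  # signed angle from vertical
    ang[len < sqrt(.Machine$double.eps)] <- NA_real_
    ang
  }
  th_t <- line_angle(frames$x_t1, frames$y_t1, frames$x_t2, frames$y_t2)
  th_h <- line_angle(frames$x_h1, frames$y_h1, frames$x_h2, frames$y_h2)
  flagged <- is.na(th_t) | is.na(th_h)
  if (mean(flagged) > max_flagged_frac)
    stop(sprintf("%.1f%% of frames have coincident markers (> %.0f%% allowed)",
                 100 * mean(flagged), 100 * max_flagged_frac), call. = FALSE)
  ok <- !flagged
  th_t[ok] <- unwrap_deg(th_t[ok])
  th_h[ok] <- unwrap_deg(th_h[ok])
  list(theta_thorax = th_t, theta_head = th_h,
       theta_head_thorax = th_h - th_t, flagged = flagged)
}

#' Analysis window into a trial
#'
#' Half-open index window `[start, start + length)` (1-based `start`) selecting
#' the samples used for spectral metrics; constructed so it spans a whole
#' number of stimulus cycles.
#'
#' @param start First sample index (1-based).
#' @param length Number of samples in the window.
#' @param n_total Total series length the window must fit in.
#' @return Object of class `"analysis_window"`.
#' @export
analysis_window <- function(start, length, n_total) {
  start <- as.integer(start); length <- as.integer(length)
  if (start < 1L || length < 1L || start + length - 1L > n_total)
    stop("window out of range", call. = FALSE)
  structure(list(start = start, length = length, n_total = as.integer(n_total)),
            class = "analysis_window")
}

#' Sample indices selected by an analysis window
#' @param window An [analysis_window()].
#' @return Integer vector of indices.
#' @export
window_indices <- function(window) {
  stopifnot(inherits(window, "analysis_window"))
  seq.int(window$start, length.out = window$length)
}

#' Exclude ramp segments and trim to whole cycles
#'
#' Drops the first and last quarter cycle (`1/(4 f)` s each) when the stimulus
#' used ramp endpoints -- those intervals do not carry the sinusoidal stimulus
#' and the matching response periods are excluded from analysis -- then trims
#' the remainder down to the largest whole number of stimulus cycles so the
#' stimulus frequency falls exactly on the DFT grid. The whole-cycle window is
#' centered in the remaining span, so the spare half cycle becomes a symmetric
#' guard interval in which the low-pass filter's smearing of the
#' ramp/sinusoid junction can decay before the window begins. An 8-cycle 2 Hz
#' trial at 1200 Hz loses at least 150 samples at each end and analyzes 7
#' whole cycles (4200 samples).
#'
#' @param x A [trial()] or a series length (number of samples).
#' @param spec The trial's [stimulus_spec()].
#' @return An [analysis_window()].
#' @export
exclude_ramps <- function(x, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- if (inherits(x, "trial")) length(x$time) else as.integer(x)
  spc <- as.integer(round(spec$sample_rate / spec$frequency))
  nq <- if (spec$ramp_endpoints) as.integer(round(spc / 4)) else 0L
  avail <- n - 2L * nq
  ncyc <- avail %/% spc
  if (ncyc < 2L)
    stop("fewer than 2 whole stimulus cycles remain after ramp exclusion",
         call. = FALSE)
  guard <- (avail - ncyc * spc) %/% 2L
  analysis_window(start = nq + guard + 1L, length = ncyc * spc, n_total = n)
}
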