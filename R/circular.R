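#' Minimal circular difference between angles
#'
#' Absolute angular separation along the shorter arc, in degrees (0 to 180).
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Non-negative differences.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular median of a set of phases
#'
#' The sample angle minimizing the sum of minimal-arc distances to all
#' samples (the standard sample circular median restricted to observed
#' angles, which makes it deterministic); ties are broken toward the smallest
#' angle in \[0, 360). Rotation-equivariant up to tie-breaking: adding a
#' constant to every phase adds it (mod 360) to the median.
#'
#' @param phases Angles in degrees; `NA` values (e.g. undefined phases of
#'   zero-gain trials) are dropped.
#' @return The circular median in degrees in \[0, 360).
#' @export
circular_median <- function(phases) {
  phases <- phases[!is.na(phases)] %% 360
  if (!length(phases)) stop("no phases to take a median of", call. = FALSE)
  cand <- sort(unique(phases))
  cost <- vapply(cand, function(a) sum(circ_diff(phases, a)), numeric(1))
  cand[which.min(cost)]  # which.min takes the first (smallest angle) on ties
}
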