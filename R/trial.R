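#' Construct a trial
#'
#' A trial is one stimulus-response recording: a uniform time base, the imposed
#' thorax roll angle, and the head-relative-to-thorax angle
#' (theta_head_thorax = theta_head - theta_thorax), all in degrees, plus
#' free-form metadata (stimulus frequency and amplitude, light condition,
#' treatment group, animal and trial identifiers, ...).
#'
#' @param time Sample times in seconds, strictly increasing and uniform.
#' @param theta_thorax Thorax roll angle series, degrees.
#' @param theta_head_thorax Head-minus-thorax angle series, degrees.
#' @param meta Named list of metadata.
#' @return An object of class `"trial"`.
#' @export
trial <- function(time, theta_thorax, theta_head_thorax, meta = list()) {
  n <- length(time)
  if (n < 2L) stop("a trial needs at least two samples", call. = FALSE)
  if (length(theta_thorax) != n || length(theta_head_thorax) != n)
    stop("angle series must have the same length as `time`", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("`time` must be uniformly sampled", call. = FALSE)
  structure(
    list(time = as.numeric(time),
         theta_thorax = as.numeric(theta_thorax),
         theta_head_thorax = as.numeric(theta_head_thorax),
         meta = meta),
    class = "trial"
  )
}

#' @export
print.trial <- function(x, ...) {
  sr <- 1 / mean(diff(x$time))
  cat(sprintf("<trial> %d samples @ %.5g Hz (%.3g s)\n",
              length(x$time), sr, diff(range(x$time))))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L,
                   logical(1))
    if (any(keep))
      cat("  meta:", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sampling rate of a trial
#' @param x A [trial()].
#' @return Sampling rate in Hz.
#' @export
trial_sample_rate <- function(x) {
  stopifnot(inherits(x, "trial"))
  1 / mean(diff(x$time))
}

#' @export
as.data.frame.trial <- function(x, ...) {
  data.frame(time_s = x$time,
             theta_thorax_deg = x$theta_thorax,
             theta_head_thorax_deg = x$theta_head_thorax)
}

#' Write a trial to delimited text
#'
#' CSV with columns `time_s, theta_thorax_deg, theta_head_thorax_deg`;
#' metadata is stored in `# key: value`-style header lines holding one JSON
#' object, so a trial file is self-describing and round-trips through
#' [read_trial()].
#'
#' @param x A [trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path) {
  stopifnot(inherits(x, "trial"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x$meta))
    writeLines(paste0("# meta: ",
                      jsonlite::toJSON(x$meta, auto_unbox = TRUE, digits = NA)),
               con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a trial written by [write_trial()]
#' @param path File path.
#' @return A [trial()].
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  meta_line <- grep("^# meta: ", lines, value = TRUE)
  if (length(meta_line))
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1L]),
                               simplifyVector = TRUE)
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  trial(df$time_s, df$theta_thorax_deg, df$theta_head_thorax_deg,
        meta = as.list(meta))
}
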