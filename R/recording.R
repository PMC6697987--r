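#' Construct a movement recording
#'
#' A `movement_recording` bundles the multichannel time series of one task
#' execution (instance) with its sampling rate and identity labels. Channels
#' are 1-D sample series of equal length, each tagged with a kind so that
#' downstream stages know how to treat them (joint angles in degrees,
#' accelerations in m/s^2, angular velocities in deg/s).
#'
#' @param channels named list of equal-length numeric vectors.
#' @param fs sampling rate in Hz. Must exceed 20 Hz so that the 2-10 Hz
#'   tremor band is resolvable.
#' @param subject_id,day_id opaque identity labels (coerced to character).
#' @param instance_id integer index of the task execution within the day.
#' @param kinds optional character vector (recycled or named like `channels`)
#'   with one of `"joint_angle"`, `"acceleration_x"`, `"acceleration_y"`,
#'   `"acceleration_z"`, `"angular_velocity_x"`, `"angular_velocity_y"`,
#'   `"angular_velocity_z"`. Defaults to `"joint_angle"`.
#' @return an object of class `movement_recording`.
#' @export
movement_recording <- function(channels, fs, subject_id = "s1", day_id = "d1",
                               instance_id = 1L, kinds = "joint_angle") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have the same number of samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  if (fs < 20)
    stop("fs must be at least 20 Hz so the 2-10 Hz tremor band is resolvable")
  valid_kinds <- c("joint_angle",
                   paste0("acceleration_", c("x", "y", "z")),
                   paste0("angular_velocity_", c("x", "y", "z")))
  kinds <- rep_len(kinds, length(channels))
  if (!all(kinds %in% valid_kinds))
    stop("invalid channel kind: ", paste(setdiff(kinds, valid_kinds), collapse = ", "))
  structure(list(subject_id = as.character(subject_id),
                 day_id = as.character(day_id),
                 instance_id = as.integer(instance_id),
                 fs = as.numeric(fs),
                 channels = lapply(channels, as.numeric),
                 kinds = stats::setNames(kinds, names(channels)),
                 n_samples = unname(lens[1])),
            class = "movement_recording")
}

#' @export
print.movement_recording <- function(x, ...) {
  cat(sprintf("<movement_recording> subject %s, day %s, instance %d\n",
              x$subject_id, x$day_id, x$instance_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.2f s)\n",
              length(x$channels), x$n_samples, x$fs, x$n_samples / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a [movement_recording()].
#' @return scalar duration in seconds.
#' @export
recording_duration <- function(recording) {
  recording$n_samples / recording$fs
}

#' Define an analysis window
#'
#' Marks the analysed movement stage (e.g. the sustained hold of a
#' finger-to-nose task) within a recording, in seconds.
#'
#' @param start_s,end_s window bounds in seconds, `0 <= start_s < end_s`.
#' @param label free-text description.
#' @return an object of class `analysis_window`.
#' @export
analysis_window <- function(start_s, end_s, label = "") {
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 || start_s >= end_s)
    stop(sprintf("invalid analysis window [%s, %s]: need 0 <= start < end",
                 format(start_s), format(end_s)))
  structure(list(start_s = start_s, end_s = end_s, label = as.character(label)),
            class = "analysis_window")
}

#' Extract annotated window segments from a recording
#'
#' Slices every channel of a recording at each annotated window. Window times
#' in seconds map to the half-open sample range
#' `[round(start_s * fs), round(end_s * fs))`.
#'
#' @param recording a [movement_recording()].
#' @param annotations list of [analysis_window()] objects (or a single one).
#' @return a list with one element per window, each a list with `label`,
#'   `start_s`, `end_s`, `duration_s`, `fs` and `channels` (the sliced
#'   series). An empty annotation list yields an empty list.
#' @export
extract_windows <- function(recording, annotations) {
  stopifnot(inherits(recording, "movement_recording"))
  if (inherits(annotations, "analysis_window")) annotations <- list(annotations)
  if (length(annotations) == 0) return(list())
  dur <- recording_duration(recording)
  lapply(annotations, function(w) {
    if (!inherits(w, "analysis_window")) w <- do.call(analysis_window, w)
    if (w$end_s > dur + 1e-9)
      stop(sprintf("window [%g, %g] ('%s') lies outside the %.3f s recording",
                   w$start_s, w$end_s, w$label, dur))
    i0 <- round(w$start_s * recording$fs)
    i1 <- round(w$end_s * recording$fs)   # exclusive
    if (i1 > recording$n_samples) i1 <- recording$n_samples
    idx <- seq.int(i0 + 1L, i1)
    list(label = w$label, start_s = w$start_s, end_s = w$end_s,
         duration_s = (i1 - i0) / recording$fs, fs = recording$fs,
         channels = lapply(recording$channels, function(ch) ch[idx]))
  })
}
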