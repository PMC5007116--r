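#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule records the start time and duration of every frame of a
#' dynamic emission scan, in seconds. Frames must be contiguous (each frame
#' starts where the previous one ends) and non-overlapping, which is how
#' dynamic brain PET protocols are specified.
#'
#' @param frame_start Numeric vector of frame start times (seconds).
#' @param frame_duration Numeric vector of frame durations (seconds), same
#'   length as `frame_start`, all positive.
#' @return An object of class `frame_schedule`: a list with elements
#'   `frame_start`, `frame_duration` and `frame_mid` (frame mid-times).
#' @examples
#' sch <- default_frame_schedule()
#' sum(sch$frame_duration) # 3630 s = 60.5 min
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration)) {
    stop("frame_start and frame_duration must have the same length")
  }
  if (length(frame_start) == 0) stop("frame schedule must have >= 1 frame")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration))) {
    stop("frame times must be finite")
  }
  if (any(frame_duration <= 0)) stop("all frame durations must be positive")
  n <- length(frame_start)
  if (n > 1) {
    gaps <- frame_start[-1] - (frame_start[-n] + frame_duration[-n])
    if (any(abs(gaps) > 1e-6)) {
      stop("frames must be contiguous and non-overlapping")
    }
  }
  structure(
    list(
      frame_start = frame_start,
      frame_duration = frame_duration,
      frame_mid = frame_start + frame_duration / 2
    ),
    class = "frame_schedule"
  )
}

#' Default 60.5-min dynamic frame schedule
#'
#' A 22-frame schedule spanning 3630 s (60.5 min):
#' 1x30 s, 6x5 s, 3x10 s, 4x60 s, 2x150 s, 2x300 s, 4x600 s. Short frames
#' bracket the bolus passage; long frames cover the slow washout tail.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(30, rep(5, 6), rep(10, 3), rep(60, 4), rep(150, 2),
           rep(300, 2), rep(600, 4))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f s total (%.2f min)\n",
              length(x$frame_start),
              sum(x$frame_duration), sum(x$frame_duration) / 60))
  invisible(x)
}

n_frames <- function(schedule) length(schedule$frame_start)

scan_end <- function(schedule) {
  n <- n_frames(schedule)
  schedule$frame_start[n] + schedule$frame_duration[n]
}

#' Write / read a frame-timing JSON sidecar
#'
#' The sidecar holds `frame_start_s` and `frame_duration_s` arrays, the
#' conventional plain-text companion of a 4D dynamic volume.
#'
#' @param schedule A [frame_schedule()].
#' @param path File path of the JSON sidecar.
#' @return `write_frame_schedule` returns `path` invisibly;
#'   `read_frame_schedule` returns a [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(
    list(frame_start_s = schedule$frame_start,
         frame_duration_s = schedule$frame_duration),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_frame_schedule
#' @export
read_frame_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$frame_start_s) || is.null(x$frame_duration_s)) {
    stop("timing JSON must contain frame_start_s and frame_duration_s")
  }
  frame_schedule(x$frame_start_s, x$frame_duration_s)
}
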