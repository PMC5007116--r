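#' Time-activity curve
#'
#' A time-activity curve (TAC) is the activity concentration of a voxel,
#' region, or blood pool sampled at a set of times — typically the frame
#' mid-times of a dynamic acquisition. Times are in seconds, values in
#' kBq/mL.
#'
#' @param times Strictly increasing numeric vector of sample times (seconds).
#' @param values Numeric vector of activity concentrations (kBq/mL), same
#'   length as `times`, all finite.
#' @return An object of class `tac`.
#' @export
tac <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (length(times) == 0) stop("a TAC needs at least one sample")
  if (any(!is.finite(times))) stop("TAC times must be finite")
  if (any(diff(times) <= 0)) stop("TAC times must be strictly increasing")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(times = times, values = values), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d samples, t = [%.1f, %.1f] s, peak %.3g kBq/mL\n",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(time_s = x$times, value_kBq_per_mL = x$values)
}

#' Trapezoid area under a TAC
#'
#' @param x A [tac()].
#' @return Trapezoid integral of `values` over `times` (kBq/mL * s).
#' @export
tac_auc <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (length(x$times) < 2) return(0)
  sum(diff(x$times) * (utils::head(x$values, -1) + utils::tail(x$values, -1)) / 2)
}

#' Write / read a TAC as TSV
#'
#' Columns are `frame_start_s`, `frame_duration_s`, `value_kBq_per_mL`; the
#' TAC samples are taken to sit at frame mid-times of `schedule`.
#'
#' @param x A [tac()] sampled at the mid-times of `schedule`.
#' @param schedule The [frame_schedule()] the TAC was averaged on.
#' @param path Output TSV path.
#' @return `write_tac_tsv` returns `path` invisibly; `read_tac_tsv` returns a
#'   list with elements `tac` and `schedule`.
#' @export
write_tac_tsv <- function(x, schedule, path) {
  stopifnot(inherits(x, "tac"), inherits(schedule, "frame_schedule"))
  if (length(x$times) != n_frames(schedule) ||
      max(abs(x$times - schedule$frame_mid)) > 1e-6) {
    stop("TAC must be sampled at the schedule's frame mid-times")
  }
  utils::write.table(
    data.frame(frame_start_s = schedule$frame_start,
               frame_duration_s = schedule$frame_duration,
               value_kBq_per_mL = x$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_tac_tsv
#' @export
read_tac_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("frame_start_s", "frame_duration_s", "value_kBq_per_mL")
  if (!all(need %in% names(d))) {
    stop("TAC TSV must have columns ", paste(need, collapse = ", "))
  }
  schedule <- frame_schedule(d$frame_start_s, d$frame_duration_s)
  list(tac = tac(schedule$frame_mid, d$value_kBq_per_mL), schedule = schedule)
}

# Linear interpolation of a TAC onto new times; 0 outside support on the
# left (before the first sample the curve is taken to rise from 0 at t = 0),
# last value carried on the right.
tac_interp <- function(x, times) {
  stopifnot(inherits(x, "tac"))
  t0 <- x$times
  v0 <- x$values
  if (t0[1] > 0) {
    t0 <- c(0, t0)
    v0 <- c(0, v0)
  }
  stats::approx(t0, v0, xout = times, rule = 2, yleft = 0)$y
}
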