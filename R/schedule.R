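#' Build an acquisition frame schedule
#'
#' Parses a compact schedule specification of the form
#' `"<count>x<seconds>,<count>x<seconds>,..."` into a contiguous sequence of
#' acquisition frames starting at time zero.  The standard 120-min protocol
#' used throughout this package is `"6x30,3x60,2x120,22x300"`: 33 frames of
#' progressively longer duration.
#'
#' Frames are half-open intervals `[start_s, end_s)` in seconds, 0-based in
#' time and 1-based in frame index.  Contiguity (no gaps, no overlap) is
#' guaranteed by construction.
#'
#' @param spec Character scalar, comma-separated `"<count>x<seconds>"` groups.
#' @return A `frame_schedule`: a data frame with columns `frame`, `start_s`,
#'   `end_s`.
#' @examples
#' sched <- build_schedule("6x30,3x60,2x120,22x300")
#' nrow(sched)              # 33 frames
#' total_duration_min(sched) # 120 min
#' @seealso [frame_mid_min()], [bin_to_frames()], [extract_window()]
#' @export
build_schedule <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec) || !nzchar(spec))
    stop("schedule spec must be a single non-empty string", call. = FALSE)
  groups <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1L]]
  if (!length(groups))
    stop("empty schedule spec", call. = FALSE)
  durs_s <- unlist(lapply(groups, function(g) {
    m <- regmatches(g, regexec("^([0-9]+)x([0-9]+(\\.[0-9]+)?)$", g))[[1L]]
    if (length(m) < 3L)
      stop(sprintf("malformed schedule group '%s': expected <count>x<seconds>", g),
           call. = FALSE)
    count <- as.integer(m[2L])
    dur <- as.numeric(m[3L])
    if (count < 1L)
      stop(sprintf("schedule group '%s' has zero count", g), call. = FALSE)
    if (dur <= 0)
      stop(sprintf("schedule group '%s' has non-positive duration", g), call. = FALSE)
    rep(dur, count)
  }))
  end_s <- cumsum(durs_s)
  out <- data.frame(frame = seq_along(durs_s),
                    start_s = c(0, end_s[-length(end_s)]),
                    end_s = end_s)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default acquisition schedule specification
#'
#' The 33-frame, 120-min dynamic protocol: 6 x 30 s, 3 x 60 s, 2 x 120 s,
#' 22 x 300 s.
#' @return Character scalar usable with [build_schedule()].
#' @export
default_schedule_spec <- function() "6x30,3x60,2x120,22x300"

as_frame_schedule <- function(x) {
  if (inherits(x, "frame_schedule")) return(x)
  if (is.character(x)) return(build_schedule(x))
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  validate_schedule_frames(x$start_s, x$end_s)
  out <- data.frame(frame = seq_len(nrow(x)), start_s = x$start_s, end_s = x$end_s)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

validate_schedule_frames <- function(start_s, end_s) {
  if (!length(start_s) || length(start_s) != length(end_s))
    stop("schedule must have matching, non-empty start/end vectors", call. = FALSE)
  if (abs(start_s[1L]) > 1e-9)
    stop("schedule must start at 0", call. = FALSE)
  if (any(end_s - start_s <= 0))
    stop("all frame durations must be positive", call. = FALSE)
  n <- length(start_s)
  if (n > 1L && any(abs(start_s[-1L] - end_s[-n]) > 1e-9))
    stop("frames must be contiguous (end of frame i = start of frame i+1)",
         call. = FALSE)
  invisible(TRUE)
}

#' Frame mid-times in minutes
#' @param schedule A `frame_schedule` (or spec string).
#' @return Numeric vector of frame mid-times (min), one per frame.
#' @export
frame_mid_min <- function(schedule) {
  schedule <- as_frame_schedule(schedule)
  (schedule$start_s + schedule$end_s) / 120
}

#' Frame durations in minutes
#' @inheritParams frame_mid_min
#' @return Numeric vector of frame durations (min).
#' @export
frame_dur_min <- function(schedule) {
  schedule <- as_frame_schedule(schedule)
  (schedule$end_s - schedule$start_s) / 60
}

#' Total schedule duration in minutes
#' @inheritParams frame_mid_min
#' @return Scalar total duration (min).
#' @export
total_duration_min <- function(schedule) {
  schedule <- as_frame_schedule(schedule)
  max(schedule$end_s) / 60
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g min total\n",
              nrow(x), total_duration_min(x)))
  invisible(x)
}

schedules_equal <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    all(abs(a$start_s - b$start_s) < tol) &&
    all(abs(a$end_s - b$end_s) < tol)
}

# Index of the frame boundary equal to t_min, or NA if no boundary matches.
# Boundaries are the n+1 values start_1, end_1, ..., end_n in minutes.
boundary_index <- function(schedule, t_min, tol = 1e-6) {
  bounds <- c(schedule$start_s[1L], schedule$end_s) / 60
  hit <- which(abs(bounds - t_min) < tol)
  if (length(hit)) hit[1L] else NA_integer_
}
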