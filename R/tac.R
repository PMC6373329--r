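#' Construct a single-region time-activity curve
#'
#' A `tac` ties frame-averaged activity concentrations (kBq/mL) for one region
#' to a frame schedule.  Values are within-frame averages, one per frame.
#'
#' @param region Region label.
#' @param schedule A `frame_schedule` (or spec string).
#' @param values Numeric vector of frame-averaged concentrations (kBq/mL).
#' @return Object of class `tac`.
#' @export
new_tac <- function(region, schedule, values) {
  schedule <- as_frame_schedule(schedule)
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop(sprintf("region '%s': %d values for %d frames", region,
                 length(values), nrow(schedule)), call. = FALSE)
  if (any(!is.finite(values)))
    stop(sprintf("region '%s': non-finite TAC values", region), call. = FALSE)
  structure(list(region = as.character(region), schedule = schedule,
                 values = values),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region '%s', %d frames, peak %.3g kBq/mL\n",
              x$region, length(x$values), max(x$values)))
  invisible(x)
}

#' Assemble a multi-region TAC table
#'
#' The long-format container used for whole-subject data: one row per region
#' and frame, matching the on-disk CSV layout
#' (`region,frame_start_s,frame_end_s,value_kbq_ml`).
#'
#' @param tacs A list of [new_tac()] objects sharing one schedule.
#' @return A `tac_table` data frame with the shared schedule attached as
#'   attribute `"schedule"`.
#' @export
tac_table <- function(tacs) {
  stopifnot(is.list(tacs), length(tacs) >= 1L)
  sched <- tacs[[1L]]$schedule
  rows <- lapply(tacs, function(tc) {
    stopifnot(inherits(tc, "tac"))
    if (!schedules_equal(tc$schedule, sched))
      stop(sprintf("region '%s' uses a different schedule", tc$region),
           call. = FALSE)
    data.frame(region = tc$region,
               frame_start_s = sched$start_s,
               frame_end_s = sched$end_s,
               value_kbq_ml = tc$values)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schedule") <- sched
  class(out) <- c("tac_table", "data.frame")
  out
}

#' Schedule of a TAC table
#' @param x A `tac_table`.
#' @return The shared `frame_schedule`.
#' @export
tac_schedule <- function(x) {
  sched <- attr(x, "schedule")
  if (is.null(sched)) {
    first <- x[x$region == x$region[1L], , drop = FALSE]
    sched <- as_frame_schedule(data.frame(start_s = first$frame_start_s,
                                          end_s = first$frame_end_s))
  }
  sched
}

#' Region labels present in a TAC table
#' @param x A `tac_table`.
#' @return Character vector of region names in order of first appearance.
#' @export
tac_regions <- function(x) unique(x$region)

#' Extract one region's TAC from a TAC table
#' @param x A `tac_table`.
#' @param region Region label.
#' @return A `tac`.
#' @export
tac_get <- function(x, region) {
  rows <- x[x$region == region, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("region '%s' not present", region), call. = FALSE)
  new_tac(region, tac_schedule(x), rows$value_kbq_ml)
}

#' Bin a continuous curve into acquisition frames
#'
#' Frame values are within-frame time-averages of the continuous curve,
#' computed by trapezoidal integration on the supplied fine grid.  Frame
#' boundaries must lie on (or within `1e-6` min of) grid nodes; the grid must
#' span the whole schedule.
#'
#' @param t_min Strictly increasing fine time grid (min), starting at 0.
#' @param values Curve values on `t_min` (kBq/mL).
#' @param schedule Target `frame_schedule` (or spec string).
#' @param region Region label for the resulting `tac`.
#' @return A `tac` of frame-averaged values.
#' @export
bin_to_frames <- function(t_min, values, schedule, region = "region") {
  schedule <- as_frame_schedule(schedule)
  stopifnot(length(t_min) == length(values), length(t_min) >= 2L)
  if (any(diff(t_min) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (max(schedule$end_s) / 60 > max(t_min) + 1e-9)
    stop("schedule extends past the time grid", call. = FALSE)
  # cumulative trapezoid on the fine grid
  ct <- c(0, cumsum(diff(t_min) * (values[-length(values)] + values[-1L]) / 2))
  at_min <- function(tq) {
    idx <- findInterval(tq + 1e-9, t_min)
    if (abs(t_min[idx] - tq) > 1e-6)
      stop(sprintf("frame boundary %.6g min not on the fine grid", tq),
           call. = FALSE)
    ct[idx]
  }
  start_min <- schedule$start_s / 60
  end_min <- schedule$end_s / 60
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    (at_min(end_min[i]) - at_min(start_min[i])) / (end_min[i] - start_min[i])
  }, numeric(1))
  new_tac(region, schedule, vals)
}

#' Truncate TACs to an earlier end time
#'
#' Drops all frames beyond `t_end_min`, e.g. to model 0-90 min of a 120-min
#' acquisition.  `t_end_min` must coincide with a frame boundary; no
#' interpolation is ever performed.
#'
#' @param x A `tac` or `tac_table`.
#' @param t_end_min End of the retained interval (min).
#' @return Object of the same class as `x` on the truncated schedule.
#' @export
truncate_to <- function(x, t_end_min) {
  if (inherits(x, "tac")) {
    sched <- x$schedule
    bi <- boundary_index(sched, t_end_min)
    if (is.na(bi))
      stop(sprintf("alignment error: %.6g min is not a frame boundary", t_end_min),
           call. = FALSE)
    keep <- sched$end_s / 60 <= t_end_min + 1e-6
    return(new_tac(x$region, sched[keep, , drop = FALSE], x$values[keep]))
  }
  stopifnot(inherits(x, "tac_table"))
  tac_table(lapply(tac_regions(x), function(r) truncate_to(tac_get(x, r), t_end_min)))
}

#' Extract a static acquisition window
#'
#' Selects the consecutive frames exactly covering
#' `[start_min, start_min + duration_min)` and returns the duration-weighted
#' mean concentration per region.  Both window bounds must coincide with frame
#' boundaries; misalignment is an error (no silent interpolation).
#'
#' @param x A `tac_table`.
#' @param start_min Window start (min); the standard choices are 30, 40, 50, 60.
#' @param duration_min Window length (min), default 30.
#' @return A `static_window`: data frame with columns `region`,
#'   `mean_kbq_ml`, plus attributes `start_min`, `end_min`, `frame_indices`.
#' @export
extract_window <- function(x, start_min, duration_min = 30) {
  stopifnot(inherits(x, "tac_table"))
  sched <- tac_schedule(x)
  end_min <- start_min + duration_min
  b0 <- boundary_index(sched, start_min)
  b1 <- boundary_index(sched, end_min)
  if (is.na(b0) || is.na(b1))
    stop(sprintf(
      "alignment error: window [%g, %g) min does not align to frame boundaries",
      start_min, end_min), call. = FALSE)
  idx <- which(sched$start_s / 60 >= start_min - 1e-6 &
                 sched$end_s / 60 <= end_min + 1e-6)
  w <- frame_dur_min(sched)[idx]
  regions <- tac_regions(x)
  means <- vapply(regions, function(r) {
    v <- tac_get(x, r)$values[idx]
    sum(w * v) / sum(w)
  }, numeric(1))
  out <- data.frame(region = regions, mean_kbq_ml = unname(means))
  attr(out, "start_min") <- start_min
  attr(out, "end_min") <- end_min
  attr(out, "frame_indices") <- idx
  class(out) <- c("static_window", "data.frame")
  out
}

#' Merge regions by weighted TAC averaging
#'
#' Combines several regions of a TAC table into a single volume-weighted
#' average TAC (equal weights by default), e.g. fusing left and right thalamus
#' into one transporter-rich region.
#'
#' @param x A `tac_table`.
#' @param regions Regions to merge.
#' @param name Label of the merged region.
#' @param weights Optional positive weights (e.g. VOI volumes), recycled to
#'   `length(regions)`; equal by default.
#' @return A `tac` for the merged region.
#' @export
merge_regions <- function(x, regions, name = "merged", weights = NULL) {
  stopifnot(length(regions) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(regions))
  weights <- rep_len(weights, length(regions))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  vals <- sapply(regions, function(r) tac_get(x, r)$values)
  new_tac(name, tac_schedule(x),
          as.numeric(vals %*% (weights / sum(weights))))
}
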