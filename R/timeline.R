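# Timeline: ordered key frames at positions measured in seconds. The
# timeline is calibrated at a fixed 30 frames per second -- a 1 s gap
# between two key frames always expands to 30 interpolated frames,
# independent of the frame rate chosen for export.

#' Create an empty timeline
#'
#' @return A `netanim_timeline` with no entries and the fixed 30 fps
#'   calibration.
#' @export
timeline <- function() {
  structure(list(entries = list(), fps_base = 30L),
            class = "netanim_timeline")
}

is_timeline <- function(x) inherits(x, "netanim_timeline")

#' @export
print.netanim_timeline <- function(x, ...) {
  cat(sprintf("<netanim timeline: %d key frames", length(x$entries)))
  if (length(x$entries)) {
    cat(sprintf(", t = %s s", paste(format(timeline_times(x)), collapse = ", ")))
  }
  cat(">\n")
  invisible(x)
}

#' Key-frame times of a timeline
#' @param tl A `netanim_timeline`.
#' @return Numeric vector of times in seconds (sorted non-decreasing).
#' @export
timeline_times <- function(tl) {
  vapply(tl$entries, function(f) f$time_s, numeric(1L))
}

timeline_ids <- function(tl) {
  vapply(tl$entries, function(f) f$frame_id, character(1L))
}

resort_timeline <- function(tl) {
  if (length(tl$entries) > 1L) {
    ord <- order(timeline_times(tl))
    tl$entries <- tl$entries[ord]
  }
  tl
}

#' Add a key frame to a timeline
#'
#' The frame is inserted preserving the time order. A frame captured with
#' an unset time is placed one second after the current last frame (or at
#' t = 0 on an empty timeline).
#'
#' @param tl A `netanim_timeline`.
#' @param frame A `netanim_keyframe`.
#' @return The updated timeline.
#' @export
add_keyframe <- function(tl, frame) {
  if (!is_timeline(tl)) stop(netanim_error("add_keyframe() expects a timeline"))
  if (!is_keyframe(frame)) stop(netanim_error("add_keyframe() expects a key frame"))
  if (is.na(frame$time_s)) {
    frame$time_s <- if (!length(tl$entries)) 0
                    else max(timeline_times(tl)) + 1.0
  }
  ids <- timeline_ids(tl)
  if (frame$frame_id %in% ids) {
    stop(netanim_error(sprintf(
      "timeline already contains a frame with id '%s'", frame$frame_id)))
  }
  tl$entries[[length(tl$entries) + 1L]] <- frame
  resort_timeline(tl)
}

#' Remove key frames by id
#'
#' @param tl A `netanim_timeline`.
#' @param ids Character vector of frame ids to remove.
#' @return The updated timeline.
#' @export
remove_keyframes <- function(tl, ids) {
  if (!is_timeline(tl)) stop(netanim_error("remove_keyframes() expects a timeline"))
  have <- timeline_ids(tl)
  missing <- setdiff(ids, have)
  if (length(missing)) {
    stop(netanim_error(sprintf("no key frame with id '%s'", missing[[1L]]),
                       class = "netanim_lookup_error"))
  }
  tl$entries <- tl$entries[!(have %in% ids)]
  tl
}

#' Remove every key frame
#' @param tl A `netanim_timeline`.
#' @return An empty timeline.
#' @export
clear_all <- function(tl) {
  if (!is_timeline(tl)) stop(netanim_error("clear_all() expects a timeline"))
  tl$entries <- list()
  tl
}

#' Move one key frame to a new time
#'
#' Retimes the identified frame and re-sorts the timeline (a frame dragged
#' past a neighbour swaps order). Coincident times are allowed; a
#' zero-length segment clamps to a single interpolation step, i.e. an
#' instantaneous cut (see [segment_counts()]).
#'
#' @param tl A `netanim_timeline`.
#' @param id Frame id.
#' @param new_time_s New position in seconds (>= 0).
#' @return The updated timeline.
#' @export
move_keyframe <- function(tl, id, new_time_s) {
  if (!is_timeline(tl)) stop(netanim_error("move_keyframe() expects a timeline"))
  if (!(is.numeric(new_time_s) && length(new_time_s) == 1L &&
        is.finite(new_time_s) && new_time_s >= 0))
    stop(netanim_error("new_time_s must be finite and >= 0",
                       class = "netanim_range_error"))
  idx <- which(timeline_ids(tl) == id)
  if (!length(idx)) {
    stop(netanim_error(sprintf("no key frame with id '%s'", id),
                       class = "netanim_lookup_error"))
  }
  tl$entries[[idx]]$time_s <- as.numeric(new_time_s)
  resort_timeline(tl)
}

#' Shift a key frame and everything after it
#'
#' Moves the identified frame and every later frame by the same amount,
#' preserving all pairwise gaps among the shifted frames exactly (the
#' shift-drag of the timeline editor).
#'
#' @param tl A `netanim_timeline`.
#' @param id Frame id of the first frame to shift.
#' @param dt_s Shift in seconds (may be negative as long as no time becomes
#'   negative).
#' @return The updated timeline.
#' @export
shift_following <- function(tl, id, dt_s) {
  if (!is_timeline(tl)) stop(netanim_error("shift_following() expects a timeline"))
  if (!(is.numeric(dt_s) && length(dt_s) == 1L && is.finite(dt_s)))
    stop(netanim_error("dt_s must be finite", class = "netanim_range_error"))
  idx <- which(timeline_ids(tl) == id)
  if (!length(idx)) {
    stop(netanim_error(sprintf("no key frame with id '%s'", id),
                       class = "netanim_lookup_error"))
  }
  sel <- seq(idx, length(tl$entries))
  new_times <- timeline_times(tl)
  new_times[sel] <- new_times[sel] + dt_s
  if (any(new_times < 0)) {
    stop(netanim_error("shift would move a key frame to a negative time",
                       class = "netanim_range_error"))
  }
  for (i in sel) tl$entries[[i]]$time_s <- new_times[[i]]
  resort_timeline(tl)
}

#' Per-segment interpolation counts at the 30 fps calibration
#'
#' Each gap between consecutive key frames expands to
#' `max(1, round(gap_seconds * 30))` interpolated frames (round half-up), so
#' key frames one second apart are separated by 30 frames. Coincident key
#' frames clamp to a single step (an instantaneous cut).
#'
#' @param tl A `netanim_timeline`.
#' @return Integer vector of length `length(entries) - 1` (empty when the
#'   timeline has fewer than two frames).
#' @export
segment_counts <- function(tl) {
  if (!is_timeline(tl)) stop(netanim_error("segment_counts() expects a timeline"))
  times <- timeline_times(tl)
  if (length(times) < 2L) return(integer())
  gaps <- diff(times)
  as.integer(pmax(1, round_half_up(gaps * tl$fps_base)))
}

#' Interpolate a timeline into a frame sequence
#'
#' Convenience pipeline: reconcile all key frames against their union
#' universe, derive per-segment counts from the timeline gaps, and expand
#' with [make_frames()].
#'
#' @param tl A `netanim_timeline` with at least one key frame.
#' @param ctrl Bezier easing control for alpha fades.
#' @return A `netanim_sequence`.
#' @export
timeline_sequence <- function(tl, ctrl = bezier_control()) {
  if (!is_timeline(tl)) stop(netanim_error("timeline_sequence() expects a timeline"))
  if (!length(tl$entries))
    stop(netanim_error("timeline has no key frames", class = "netanim_range_error"))
  rec <- reconcile_timeline(tl$entries)
  counts <- segment_counts(tl)
  if (!length(counts)) counts <- integer()
  make_frames(rec$frames, if (length(counts)) counts else 30L, ctrl)
}
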