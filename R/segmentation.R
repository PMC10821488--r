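# Movement segmentation: maximal runs of |speed| above a threshold, with
# short runs discarded, then ground-truth labelling from the annotation
# track by majority temporal overlap.

#' Segmentation configuration
#'
#' @param speed_threshold Speed (m/s) a sample must strictly exceed in
#'   magnitude to count as moving (default 0.1).
#' @param min_duration Minimum segment duration in seconds (default 2).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(speed_threshold = 0.1, min_duration = 2) {
  if (speed_threshold < 0) stop("speed_threshold must be >= 0")
  if (min_duration <= 0) stop("min_duration must be > 0")
  structure(list(speed_threshold = speed_threshold,
                 min_duration = min_duration),
            class = "segmentation_config")
}

#' Detect movement segments in a kinematic series
#'
#' A segment is a maximal contiguous run of samples with `|speed| >
#' speed_threshold`; runs spanning less than `min_duration` seconds are
#' discarded. Absolute speed is used so that backward driving counts as
#' movement. Comparisons are strict.
#'
#' @param kin A `kinematic_series` (or any data frame with `time` and
#'   `speed` columns).
#' @param cfg A [segmentation_config].
#' @return Data frame with one row per segment: `start`, `end` (seconds),
#'   `first`, `last` (sample indices, inclusive), `duration`, `label`
#'   (initialised `"unknown"`).
#' @export
detect_segments <- function(kin, cfg = segmentation_config()) {
  stopifnot(is.data.frame(kin), all(c("time", "speed") %in% names(kin)))
  n <- nrow(kin)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      first = integer(0), last = integer(0),
                      duration = numeric(0), label = character(0))
  if (n == 0L) return(empty)
  moving <- abs(kin$speed) > cfg$speed_threshold
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  first <- starts[keep]; last <- ends[keep]
  if (!length(first)) return(empty)
  dur <- kin$time[last] - kin$time[first]
  ok <- dur >= cfg$min_duration
  first <- first[ok]; last <- last[ok]
  if (!length(first)) return(empty)
  data.frame(start = kin$time[first], end = kin$time[last],
             first = first, last = last,
             duration = kin$time[last] - kin$time[first],
             label = "unknown")
}

#' Attach annotation labels to detected segments
#'
#' Each segment receives the label (active or passive) whose annotated
#' intervals cover the largest share of the segment's duration. A tie or
#' zero coverage yields `"unknown"`; such segments are excluded from
#' training downstream.
#'
#' @param segments Data frame from [detect_segments].
#' @param track An [annotation_track].
#' @return `segments` with `label`, `participant_id` and `diagnosis`
#'   columns filled in.
#' @export
label_segments <- function(segments, track) {
  stopifnot(is.data.frame(segments), inherits(track, "annotation_track"))
  lab <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s0 <- segments$start[i]; s1 <- segments$end[i]
    ov <- pmax(0, pmin(track$end, s1) - pmax(track$start, s0))
    cover <- c(active = sum(ov[track$label == "active"]),
               passive = sum(ov[track$label == "passive"]))
    lab[i] <- if (max(cover) <= 0 || cover["active"] == cover["passive"]) {
      "unknown"
    } else {
      names(cover)[which.max(cover)]
    }
  }
  segments$label <- lab
  segments$participant_id <- attr(track, "participant_id")
  segments$diagnosis <- attr(track, "diagnosis")
  segments
}
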