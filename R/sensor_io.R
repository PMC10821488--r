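# Reading, validating and synchronizing raw IMU streams and annotation
# tracks. The on-disk dialects are defined here: a JSON array of records
# {"t_ms": int, "gyro": [x,y,z] deg/s, "acc": [x,y,z] m/s^2}, or an
# equivalent CSV with columns t_ms,gx,gy,gz,ax,ay,az. Angular units are
# degrees/second at every interface.

#' Construct an IMU stream
#'
#' Container for one 6-axis inertial sensor recording: timestamps in
#' seconds, a 3-axis gyroscope in degrees/second and a 3-axis accelerometer
#' in m/s^2, all sampled nominally at `sample_rate` Hz.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param gyro Numeric n x 3 matrix of angular rates (deg/s), sensor axes
#'   x, y, z.
#' @param accel Numeric n x 3 matrix of specific force (m/s^2), sensor axes.
#' @param sensor_role `"wheel"` or `"frame"`.
#' @param sample_rate Nominal sampling rate in Hz (default 50).
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(time, gyro, accel, sensor_role = c("wheel", "frame"),
                       sample_rate = 50) {
  sensor_role <- match.arg(sensor_role)
  time <- as.numeric(time)
  gyro <- as.matrix(gyro)
  accel <- as.matrix(accel)
  if (ncol(gyro) != 3L || ncol(accel) != 3L) {
    stop("gyro and accel must have 3 columns (x, y, z)")
  }
  if (nrow(gyro) != length(time) || nrow(accel) != length(time)) {
    stop("gyro and accel must have one row per timestamp")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop(sprintf("timestamps must be strictly increasing (violation at sample %d, t = %.6f)",
                 bad, time[bad]))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be > 0")
  }
  if (anyNA(gyro) || anyNA(accel) || anyNA(time)) {
    stop("IMU stream contains missing values")
  }
  colnames(gyro) <- c("x", "y", "z")
  colnames(accel) <- c("x", "y", "z")
  structure(
    list(time = time, gyro = gyro, accel = accel,
         sensor_role = sensor_role, sample_rate = sample_rate),
    class = "imu_stream"
  )
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream role=%s n=%d rate=%g Hz span=[%.2f, %.2f] s>\n",
              x$sensor_role, length(x$time), x$sample_rate,
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA))
  invisible(x)
}

#' @export
length.imu_stream <- function(x) length(x$time)

#' Wheelchair geometry
#'
#' @param wheel_diameter Rear-wheel diameter in meters.
#' @param track_width Lateral distance between the rear wheel contact points
#'   in meters.
#' @param sensor_side Which rear wheel carries the hub sensor.
#' @return An object of class `wheelchair_geometry`.
#' @export
wheelchair_geometry <- function(wheel_diameter = 0.6, track_width = 0.56,
                                sensor_side = c("right", "left")) {
  sensor_side <- match.arg(sensor_side)
  if (wheel_diameter <= 0 || track_width <= 0) {
    stop("wheel_diameter and track_width must be > 0")
  }
  structure(list(wheel_diameter = wheel_diameter, track_width = track_width,
                 sensor_side = sensor_side),
            class = "wheelchair_geometry")
}

#' Annotation track of timed propulsion intervals
#'
#' Manually annotated intervals of active (self-propelled) or passive
#' (attendant-pushed) wheelchair use. Time not covered by any interval is
#' legal and means "unknown". Intervals are sorted by start time.
#'
#' @param intervals Data frame with columns `start`, `end` (seconds) and
#'   `label` (`"active"` or `"passive"`).
#' @param participant_id Identifier of the participant.
#' @param diagnosis `"stroke"` or `"amputation"`.
#' @param propulsion_mode Free-text description of the propulsion style.
#' @return An object of class `annotation_track` (a data frame with
#'   metadata attributes).
#' @export
annotation_track <- function(intervals, participant_id = "P0",
                             diagnosis = c("stroke", "amputation"),
                             propulsion_mode = "") {
  diagnosis <- match.arg(diagnosis)
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "label") %in% names(intervals)))
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  intervals$label <- as.character(intervals$label)
  bad_lab <- setdiff(unique(intervals$label), c("active", "passive"))
  if (length(bad_lab)) {
    stop("unknown annotation label(s): ", paste(bad_lab, collapse = ", "))
  }
  if (any(intervals$start >= intervals$end)) {
    stop("every annotation interval must satisfy start < end")
  }
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)])) {
    stop("annotation intervals must not overlap")
  }
  structure(intervals,
            participant_id = as.character(participant_id),
            diagnosis = diagnosis,
            propulsion_mode = as.character(propulsion_mode),
            class = c("annotation_track", "data.frame"))
}

# ---- file dialects ---------------------------------------------------------

#' Read a raw IMU file
#'
#' Accepts the canonical JSON dialect (array of records with fields `t_ms`,
#' `gyro`, `acc`) or the CSV mirror (`t_ms,gx,gy,gz,ax,ay,az`). Timestamps
#' are converted from milliseconds to seconds.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @param sensor_role `"wheel"` or `"frame"`.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @param sample_rate Nominal sampling rate in Hz.
#' @return An [imu_stream].
#' @export
read_imu <- function(path, sensor_role = c("wheel", "frame"),
                     format = c("auto", "json", "csv"), sample_rate = 50) {
  sensor_role <- match.arg(sensor_role)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    recs <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                     error = function(e) stop("malformed IMU JSON in ", path,
                                              ": ", conditionMessage(e)))
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      if (!all(c("t_ms", "gyro", "acc") %in% names(r)) ||
          length(r$gyro) != 3L || length(r$acc) != 3L) {
        stop(sprintf("malformed IMU record %d in %s (need t_ms, gyro[3], acc[3])",
                     i, path))
      }
    }
    t <- vapply(recs, function(r) as.numeric(r$t_ms), 0) / 1000
    gyro <- t(vapply(recs, function(r) as.numeric(r$gyro), numeric(3)))
    accel <- t(vapply(recs, function(r) as.numeric(r$acc), numeric(3)))
  } else {
    df <- utils::read.csv(path)
    need <- c("t_ms", "gx", "gy", "gz", "ax", "ay", "az")
    if (!all(need %in% names(df))) {
      stop("malformed IMU CSV in ", path, ": need columns ",
           paste(need, collapse = ","))
    }
    t <- df$t_ms / 1000
    gyro <- as.matrix(df[, c("gx", "gy", "gz")])
    accel <- as.matrix(df[, c("ax", "ay", "az")])
  }
  imu_stream(t, gyro, accel, sensor_role, sample_rate)
}

#' Write an IMU stream to disk
#'
#' @param stream An [imu_stream].
#' @param path Output path.
#' @param format `"json"` or `"csv"`; `"auto"` decides by extension.
#' @return `path`, invisibly.
#' @export
write_imu <- function(stream, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  t_ms <- round(stream$time * 1000)
  if (format == "json") {
    recs <- lapply(seq_along(stream$time), function(i) {
      list(t_ms = t_ms[i],
           gyro = round(unname(stream$gyro[i, ]), 6),
           acc = round(unname(stream$accel[i, ]), 6))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(t_ms = t_ms,
                     gx = round(stream$gyro[, 1], 6),
                     gy = round(stream$gyro[, 2], 6),
                     gz = round(stream$gyro[, 3], 6),
                     ax = round(stream$accel[, 1], 6),
                     ay = round(stream$accel[, 2], 6),
                     az = round(stream$accel[, 3], 6))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an annotation CSV
#'
#' Expects columns `start_s,end_s,label,participant_id,diagnosis,
#' propulsion_mode`. Rows may be in any time order; the returned track is
#' sorted. Overlapping intervals or unknown labels are errors.
#'
#' @param path Path to the annotation CSV.
#' @return An [annotation_track].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns start_s,end_s,label")
  }
  annotation_track(
    data.frame(start = df$start_s, end = df$end_s, label = df$label),
    participant_id = if ("participant_id" %in% names(df)) df$participant_id[1] else "P0",
    diagnosis = if ("diagnosis" %in% names(df)) df$diagnosis[1] else "stroke",
    propulsion_mode = if ("propulsion_mode" %in% names(df)) df$propulsion_mode[1] else ""
  )
}

#' Write an annotation track to CSV
#'
#' @param track An [annotation_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  df <- data.frame(start_s = track$start, end_s = track$end,
                   label = track$label,
                   participant_id = attr(track, "participant_id"),
                   diagnosis = attr(track, "diagnosis"),
                   propulsion_mode = attr(track, "propulsion_mode"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- synchronization -------------------------------------------------------

#' Synchronize two IMU streams onto a shared 50 Hz clock
#'
#' Both streams are resampled by linear interpolation onto the wheel
#' sensor's nominal-rate grid restricted to the temporal overlap. The
#' sensors are assumed hardware-synchronized; no cross-correlation
#' alignment is attempted.
#'
#' @param wheel,frame [imu_stream] objects that overlap in time by at
#'   least `min_overlap` seconds.
#' @param min_overlap Minimum required overlap in seconds (default 2).
#' @return A list with elements `wheel` and `frame`, equal-length streams
#'   on the shared grid.
#' @export
synchronize <- function(wheel, frame, min_overlap = 2) {
  stopifnot(inherits(wheel, "imu_stream"), inherits(frame, "imu_stream"))
  t0 <- max(min(wheel$time), min(frame$time))
  t1 <- min(max(wheel$time), max(frame$time))
  if (t1 - t0 < min_overlap) {
    stop(sprintf("streams overlap by %.3f s; need at least %g s", t1 - t0,
                 min_overlap))
  }
  dt <- 1 / wheel$sample_rate
  # grid anchored on the wheel sensor's own sample times
  i0 <- ceiling(round((t0 - wheel$time[1]) / dt, 9))
  grid <- wheel$time[1] + dt * seq(i0, floor(round((t1 - wheel$time[1]) / dt, 9)))
  grid <- grid[grid >= t0 - 1e-9 & grid <= t1 + 1e-9]
  resample <- function(s) {
    g <- apply(s$gyro, 2, function(col) {
      stats::approx(s$time, col, xout = grid, rule = 2)$y
    })
    a <- apply(s$accel, 2, function(col) {
      stats::approx(s$time, col, xout = grid, rule = 2)$y
    })
    imu_stream(grid, g, a, s$sensor_role, wheel$sample_rate)
  }
  list(wheel = resample(wheel), frame = resample(frame))
}
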