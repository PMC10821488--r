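# Wheelchair kinematics from raw sensor streams.
#
# Conventions (configurable via wheelchair_geometry$sensor_side):
#   - wheel sensor x-axis along the axle; positive gyro x = forward wheel
#     spin on the right wheel;
#   - frame sensor z-axis vertical up;
#   - positive yaw = counter-clockwise seen from above (left turn).
# With the sensor on the right wheel, the sensed wheel is on the outside of
# a positive-yaw turn, so chair-center speed = wheel speed - yaw * track/2.

#' Estimate and remove the constant gyroscope bias
#'
#' The per-axis bias is the mean gyro value over periods of no motion -
#' sustained runs of samples whose gyro magnitude stays below
#' `motion_threshold` - and is subtracted from every sample of that axis.
#' Sub-threshold blips shorter than `min_still_duration` (e.g. the instant
#' a speed ramp crosses zero) do not count as stationary. The
#' accelerometer is left untouched. If no sample qualifies the stream is
#' returned unchanged with a warning.
#'
#' @param stream An [imu_stream].
#' @param motion_threshold Gyro magnitude below which a sample counts as
#'   stationary, in deg/s (default 5).
#' @param min_still_duration Minimum length of a no-motion period in
#'   seconds (default 0.5).
#' @param still Optional logical mask overriding the detection, e.g. a
#'   no-motion mask derived from the wheel sensor for a frame stream
#'   (straight-line driving keeps a frame gyro near zero, so its own
#'   magnitude cannot reveal motion).
#' @return The bias-corrected [imu_stream].
#' @export
correct_gyro_offset <- function(stream, motion_threshold = 5,
                                min_still_duration = 0.5, still = NULL) {
  stopifnot(inherits(stream, "imu_stream"))
  if (is.null(still)) {
    still <- stationary_mask_(stream, motion_threshold, min_still_duration)
  }
  if (!any(still)) {
    warning("no stationary samples (gyro magnitude < ",
            motion_threshold, " deg/s); gyro offset not corrected")
    return(stream)
  }
  bias <- colMeans(stream$gyro[still, , drop = FALSE])
  out <- stream
  out$gyro <- sweep(stream$gyro, 2, bias)
  out
}

# sustained runs of sub-threshold gyro magnitude, eroded at their edges so
# the transition samples into/out of motion are not treated as rest
#' @noRd
stationary_mask_ <- function(stream, motion_threshold = 5,
                             min_still_duration = 0.5) {
  below <- sqrt(rowSums(stream$gyro^2)) < motion_threshold
  min_run <- ceiling(min_still_duration * stream$sample_rate)
  trim <- ceiling(0.2 * stream$sample_rate)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  mask <- logical(length(below))
  for (i in which(keep)) {
    a <- if (starts[i] == 1L) starts[i] else starts[i] + trim
    b <- if (ends[i] == length(below)) ends[i] else ends[i] - trim
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

#' Signed wheel-rim forward speed from the wheel gyroscope
#'
#' `v_wheel = omega_roll [rad/s] * wheel radius`, positive for forward
#' motion of the sensed wheel.
#'
#' @param wheel Offset-corrected wheel [imu_stream].
#' @param geometry A [wheelchair_geometry].
#' @return Numeric vector of wheel speed in m/s.
#' @export
wheel_speed <- function(wheel, geometry) {
  stopifnot(inherits(wheel, "imu_stream"))
  if (geometry$wheel_diameter <= 0) stop("wheel_diameter must be > 0")
  s <- if (geometry$sensor_side == "right") 1 else -1
  s * wheel$gyro[, 1] * DEG2RAD * (geometry$wheel_diameter / 2)
}

#' Chair-center forward speed from wheel speed and yaw rate
#'
#' During a turn the sensed wheel travels faster or slower than the chair
#' center by `yaw_rate * track_width / 2`; the correction sign depends on
#' which side carries the sensor.
#'
#' @param v_wheel Wheel speed series in m/s.
#' @param yaw_rate Chair yaw rate series in deg/s (positive = left turn).
#' @param geometry A [wheelchair_geometry].
#' @return Chair-center speed series in m/s.
#' @export
chair_speed <- function(v_wheel, yaw_rate, geometry) {
  if (length(v_wheel) != length(yaw_rate)) {
    stop("v_wheel and yaw_rate must have equal length")
  }
  s <- if (geometry$sensor_side == "right") 1 else -1
  v_wheel - s * yaw_rate * DEG2RAD * (geometry$track_width / 2)
}

#' Yaw rate from the frame sensor (S2 configuration)
#'
#' With the frame sensor mounted z-up, the chair yaw rate is the frame
#' gyroscope's vertical (z) component.
#'
#' @param frame Offset-corrected frame [imu_stream].
#' @return Yaw rate series in deg/s.
#' @export
yaw_rate_from_frame <- function(frame) {
  if (is.null(frame)) {
    stop("no frame stream available; use the wheel-only (S1) decomposition")
  }
  stopifnot(inherits(frame, "imu_stream"))
  frame$gyro[, 3]
}

#' Decompose the spinning wheel sensor into roll, pitch and yaw (S1)
#'
#' The wheel sensor rotates with the wheel, so chair yaw and pitch appear
#' in its y/z gyro channels modulated by the wheel angle theta. Theta is
#' tracked by a complementary filter fusing gyro integration with the
#' accelerometer's gravity direction in the sensor y-z plane
#' (`theta_a = atan2(acc_y, acc_z)`):
#' `theta <- (1 - k) * (theta + gx * dt) + k * theta_a`.
#' The de-rotated rates are then
#' `yaw = gy * sin(theta) + gz * cos(theta)` and
#' `pitch = -gy * cos(theta) + gz * sin(theta)`; roll is gyro x directly.
#' Samples with near-free-fall acceleration (magnitude < 2 m/s^2) carry no
#' usable gravity reference and fall back to gyro-only integration.
#'
#' @param wheel Offset-corrected wheel [imu_stream].
#' @param gain Complementary-filter accelerometer gain per sample
#'   (default 0.02 at 50 Hz, about a 1 s time constant).
#' @return A list with numeric series `roll_rate`, `pitch_rate`,
#'   `yaw_rate` (deg/s) and `wheel_angle` (unwrapped degrees).
#' @export
decompose_wheel_gyro <- function(wheel, gain = 0.02) {
  stopifnot(inherits(wheel, "imu_stream"))
  n <- length(wheel$time)
  gx <- wheel$gyro[, 1]; gy <- wheel$gyro[, 2]; gz <- wheel$gyro[, 3]
  acc_mag <- sqrt(rowSums(wheel$accel^2))
  freefall <- acc_mag < 2
  theta_a <- atan2(wheel$accel[, 2], wheel$accel[, 3]) * RAD2DEG
  dt <- c(0, diff(wheel$time))
  # gyro-only integral: the unwrapping reference for the accel angle
  theta_g <- cumsum(gx * dt)
  theta_a_u <- theta_a + 360 * round((theta_g - theta_a) / 360)
  theta_a_u[1] <- theta_a[1] + 360 * round((theta_g[1] - theta_a[1]) / 360)
  if (any(freefall)) {
    wm_log_("%d samples with |acc| < 2 m/s^2: holding gyro-only wheel angle there",
            sum(freefall))
    theta <- numeric(n)
    theta[1] <- if (freefall[1]) theta_g[1] else
      (1 - gain) * theta_g[1] + gain * theta_a_u[1]
    for (i in 2:n) {
      pred <- theta[i - 1] + gx[i] * dt[i]
      theta[i] <- if (freefall[i]) pred else
        (1 - gain) * pred + gain * (theta_a[i] + 360 * round((pred - theta_a[i]) / 360))
    }
  } else {
    # constant-gain recursion: theta_i = (1-k) theta_{i-1} + u_i
    u <- (1 - gain) * gx * dt + gain * theta_a_u
    u[1] <- (1 - gain) * theta_g[1] + gain * theta_a_u[1]
    theta <- as.numeric(stats::filter(u, 1 - gain, method = "recursive"))
  }
  th <- theta * DEG2RAD
  list(roll_rate = gx,
       pitch_rate = -gy * cos(th) + gz * sin(th),
       yaw_rate = gy * sin(th) + gz * cos(th),
       wheel_angle = theta)
}

#' Smoothed numerical derivative of a uniformly sampled series
#'
#' A zero-phase second-order Butterworth low-pass at `cutoff` Hz is applied
#' forward-backward, then the derivative is taken by central differences
#' (one-sided at the endpoints). Series shorter than the filter warm-up
#' (9 samples) skip the filter.
#'
#' @param x Numeric series.
#' @param time Timestamps in seconds, uniformly spaced.
#' @param cutoff Low-pass cutoff in Hz (default 6; propulsion content sits
#'   below about 3 Hz).
#' @return Numeric derivative series, same length as `x`.
#' @export
differentiate <- function(x, time, cutoff = 6) {
  n <- length(x)
  if (n != length(time)) stop("x and time must have equal length")
  if (n < 2L) return(numeric(n))
  dt <- stats::median(diff(time))
  fs <- 1 / dt
  if (n >= 9L && cutoff < fs / 2) {
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    # odd-reflection padding suppresses filtfilt edge transients and is
    # exact for constant and linear trends
    L <- min(n - 1L, 100L)
    pad <- c(2 * x[1] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
    x <- signal::filtfilt(bf, pad)[(L + 1L):(L + n)]
  } else if (n < 9L) {
    wm_log_("series of length %d below filter warm-up; raw differences used", n)
  }
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (time[2] - time[1])
  d[n] <- (x[n] - x[n - 1]) / (time[n] - time[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (time[i + 1] - time[i - 1])
  }
  d
}

#' Full kinematic reconstruction for one trial
#'
#' Runs offset correction, forward-speed and yaw-rate estimation and
#' smoothed differentiation, producing the wheelchair-level kinematic
#' series for either sensor configuration: `"S1"` (wheel sensor only, yaw
#' via the complementary-filter decomposition) or `"S2"` (wheel + frame,
#' yaw from the frame gyro's vertical axis).
#'
#' @param wheel Wheel [imu_stream] (raw; offset correction is applied).
#' @param frame Frame [imu_stream] or `NULL` (required for `"S2"`).
#' @param geometry A [wheelchair_geometry].
#' @param variant `"S1"` or `"S2"`.
#' @param offset_correct Apply [correct_gyro_offset] first (default TRUE).
#' @return A `kinematic_series`: data frame with columns `time`, `speed`
#'   (chair-center, m/s, signed), `accel` (m/s^2), `roll_rate`,
#'   `pitch_rate`, `yaw_rate` (deg/s), `roll_accel`, `pitch_accel`,
#'   `yaw_accel` (deg/s^2) and `wheel_angle` (deg), with attribute
#'   `variant`.
#' @export
compute_kinematics <- function(wheel, frame = NULL, geometry,
                               variant = c("S2", "S1"),
                               offset_correct = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(wheel, "imu_stream"), inherits(geometry, "wheelchair_geometry"))
  if (variant == "S2" && is.null(frame)) {
    stop("variant S2 requires a frame stream; none supplied")
  }
  if (!is.null(frame)) {
    sync <- synchronize(wheel, frame)
    wheel <- sync$wheel; frame <- sync$frame
  }
  if (offset_correct) {
    # the wheel gyro spins whenever the chair moves, so its no-motion mask
    # is reliable; reuse it for the frame sensor, which cannot see
    # straight-line motion in its own gyro
    still <- stationary_mask_(wheel)
    wheel <- correct_gyro_offset(wheel, still = still)
    if (!is.null(frame)) frame <- correct_gyro_offset(frame, still = still)
  }
  v_wheel <- wheel_speed(wheel, geometry)
  if (variant == "S2") {
    yaw <- yaw_rate_from_frame(frame)
    dec <- decompose_wheel_gyro(wheel)
    roll <- dec$roll_rate; pitch <- dec$pitch_rate
    wheel_angle <- dec$wheel_angle
  } else {
    dec <- decompose_wheel_gyro(wheel)
    yaw <- dec$yaw_rate; roll <- dec$roll_rate; pitch <- dec$pitch_rate
    wheel_angle <- dec$wheel_angle
  }
  v <- chair_speed(v_wheel, yaw, geometry)
  kin <- data.frame(
    time = wheel$time,
    speed = v,
    accel = differentiate(v, wheel$time),
    roll_rate = roll,
    pitch_rate = pitch,
    yaw_rate = yaw,
    roll_accel = differentiate(roll, wheel$time),
    pitch_accel = differentiate(pitch, wheel$time),
    yaw_accel = differentiate(yaw, wheel$time),
    wheel_angle = wheel_angle
  )
  structure(kin, variant = variant,
            streams = list(wheel = wheel, frame = frame),
            class = c("kinematic_series", "data.frame"))
}

#' Dead-reckoned 2D path from a kinematic series
#'
#' Heading is the integral of the yaw rate (`psi(0) = 0`); position follows
#' by Euler integration of `v * cos(psi)`, `v * sin(psi)` at the sampling
#' rate. Total distance is the integral of `|v|`.
#'
#' @param kin A `kinematic_series`.
#' @return A data frame `x`, `y` (m), `heading` (deg), with attribute
#'   `distance` (m).
#' @export
reconstruct_path <- function(kin) {
  stopifnot(inherits(kin, "kinematic_series"))
  t <- kin$time
  psi <- cumtrapz_(t, kin$yaw_rate)          # degrees
  dtv <- c(diff(t), 0)
  vx <- kin$speed * cos(psi * DEG2RAD)
  vy <- kin$speed * sin(psi * DEG2RAD)
  n <- length(t)
  x <- c(0, cumsum(vx[-n] * diff(t)))
  y <- c(0, cumsum(vy[-n] * diff(t)))
  structure(data.frame(x = x, y = y, heading = psi),
            distance = trapz_(t, abs(kin$speed)),
            class = c("path2d", "data.frame"))
}
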