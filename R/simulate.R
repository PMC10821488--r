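# Synthetic wheelchair trials: ground-truth trajectories for a
# semi-structured rehabilitation course (9 m slow / normal / slalom /
# stop-go bouts plus free movement), rendered into raw wheel- and
# frame-sensor IMU streams by inverting the kinematic model, with
# annotations carrying the true propulsion labels.
#
# Physics is planar and slip-free. Default style parameters are calibrated
# to a rehabilitation cohort: self-propulsion around 0.68 m/s after
# amputation and 0.56 m/s after stroke, attendant pushing around 1.3 m/s,
# overall moving speed near 0.86 m/s, and roughly 950 segments with a
# 55/45 active/passive mix over 24 participants.

#' Propulsion style parameters
#'
#' @param kind One of `"active_bimanual"`, `"active_one_hand_one_foot"`,
#'   `"active_backward_foot"`, `"passive_attendant"`.
#' @param push_frequency Push (or attendant sway) frequency in Hz.
#' @param speed_oscillation_fraction Relative amplitude of the
#'   push-synchronous speed oscillation, in [0, 1).
#' @param yaw_jitter_sd Standard deviation of the smooth steering jitter,
#'   deg/s.
#' @param mean_speed Cruise speed of the style, m/s.
#' @param wobble_amp Amplitude of the push-locked yaw wobble, deg/s
#'   (nonzero for one-hand-one-foot propulsion).
#' @param sway_amp Amplitude of the slow attendant sway in yaw, deg/s.
#' @param direction +1 forward, -1 backward driving.
#' @return An object of class `propulsion_style`.
#' @export
propulsion_style <- function(kind = c("active_bimanual",
                                      "active_one_hand_one_foot",
                                      "active_backward_foot",
                                      "passive_attendant"),
                             push_frequency = NULL,
                             speed_oscillation_fraction = NULL,
                             yaw_jitter_sd = NULL,
                             mean_speed = NULL,
                             wobble_amp = NULL,
                             sway_amp = NULL,
                             direction = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    active_bimanual = list(f = 1.0, osc = 0.25, jit = 4.0, v = 0.68,
                           wob = 0, sway = 0, dir = 1),
    active_one_hand_one_foot = list(f = 0.8, osc = 0.22, jit = 6.0, v = 0.60,
                                    wob = 8, sway = 0, dir = 1),
    active_backward_foot = list(f = 0.9, osc = 0.18, jit = 4.0, v = 0.55,
                                wob = 0, sway = 0, dir = -1),
    passive_attendant = list(f = 0.9, osc = 0.05, jit = 1.5, v = 1.3,
                             wob = 0, sway = 2.5, dir = 1))
  st <- list(kind = kind,
             push_frequency = push_frequency %||% defaults$f,
             speed_oscillation_fraction =
               speed_oscillation_fraction %||% defaults$osc,
             yaw_jitter_sd = yaw_jitter_sd %||% defaults$jit,
             mean_speed = mean_speed %||% defaults$v,
             wobble_amp = wobble_amp %||% defaults$wob,
             sway_amp = sway_amp %||% defaults$sway,
             direction = direction %||% defaults$dir)
  if (st$push_frequency <= 0) stop("push_frequency must be > 0")
  if (st$speed_oscillation_fraction < 0 || st$speed_oscillation_fraction >= 1) {
    stop("speed_oscillation_fraction must be in [0, 1)")
  }
  structure(st, class = "propulsion_style")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sensor noise model
#'
#' @param gyro_sd Gyro white-noise SD, deg/s.
#' @param accel_sd Accelerometer white-noise SD, m/s^2.
#' @param bias_range Constant gyro bias drawn uniformly in
#'   `[-bias_range, bias_range]` deg/s per axis per trial.
#' @return An object of class `imu_noise`.
#' @export
imu_noise <- function(gyro_sd = 0.5, accel_sd = 0.05, bias_range = 2) {
  structure(list(gyro_sd = gyro_sd, accel_sd = accel_sd,
                 bias_range = bias_range), class = "imu_noise")
}

#' The semi-structured test protocol as a bout table
#'
#' Four 9 m bouts (slow, normal speed, slalom, and a bout with two
#' intermediate stops), each with a rest gap after it.
#'
#' @param style A [propulsion_style] used for every bout.
#' @param distance Bout distance in meters (default 9).
#' @return Data frame of bouts with columns `bout`, `kind`, `distance`,
#'   `speed_factor`, `rest_after` and a list-column `style`.
#' @export
protocol_script <- function(style, distance = 9) {
  data.frame(bout = c("slow_9m", "normal_9m", "slalom_9m", "stop_go_9m"),
             kind = c("straight", "straight", "slalom", "stop_go"),
             distance = distance,
             speed_factor = c(0.65, 1.3, 1.0, 1.0),
             rest_after = c(3, 3, 3, 3)) |>
    within(style <- I(rep(list(style), 4L)))
}

#' @noRd
smooth_jitter_ <- function(n, sd, dt, tau = 0.25) {
  if (sd <= 0 || n < 2L) return(numeric(n))
  # AR(1) with correlation time tau, rescaled to the requested SD
  a <- exp(-dt / tau)
  x <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
  s <- stats::sd(x)
  if (s > 0) x * sd / s else x
}

#' @noRd
bout_speed_profile_ <- function(distance, cruise, dt, t_ramp = 1.2) {
  cruise_time <- distance / cruise - t_ramp
  if (cruise_time < 0.5) {
    cruise <- distance / (t_ramp + 0.5)
    cruise_time <- 0.5
  }
  total <- 2 * t_ramp + cruise_time
  t <- seq(0, total, by = dt)
  v <- pmin(1, pmin(t, total - t) / t_ramp) * cruise
  list(t = t, v = pmax(v, 0))
}

#' Simulate a ground-truth trajectory for a bout script
#'
#' Each bout gets a trapezoidal speed profile to its cruise speed,
#' multiplied by a propulsion oscillation `1 + osc * sin(2 pi f t)` with
#' per-cycle amplitude jitter: push-synchronous for active styles, at the
#' attendant's step cadence (0.7-1.1 Hz, much smaller amplitude) for
#' passive bouts. Cruise speed, oscillation depth, cadence and steering
#' jitter are re-drawn per bout (lognormal spread), and occasional
#' minority modes occur: self-propellers sometimes push once and coast,
#' attendants sometimes stroll slowly. The backward-foot style drives in
#' reverse (negative speed). Yaw combines smooth steering jitter, a
#' sinusoidal slalom where scripted, a push-locked wobble for
#' one-hand-one-foot propulsion, a slow attendant sway, and large
#' class-independent steering excursions during free roaming. Stop-go
#' bouts insert two decelerations to below 0.1 m/s. Bouts are separated by
#' stationary rest gaps.
#'
#' @param script Bout table from [protocol_script] (or rows of the same
#'   shape).
#' @param seed Integer seed.
#' @param dt Sample interval in seconds (default 0.02, i.e. 50 Hz).
#' @param lead_rest Stationary time before the first bout, seconds.
#' @return A `kinematic_series`-shaped data frame `time`, `speed`,
#'   `yaw_rate`, `pitch_rate` with attributes `annotations` (data frame
#'   `start`, `end`, `label`) and `bouts` (per-bout realized parameters:
#'   `cruise`, `osc`, `freq`, `yaw_jitter`, `mode`).
#' @export
simulate_trajectory <- function(script, seed = 1L, dt = 0.02, lead_rest = 3) {
  stopifnot(is.data.frame(script), nrow(script) >= 1L)
  local_seed_(child_seed_(seed, "trajectory"), {
    v_all <- numeric(0); w_all <- numeric(0)
    ann <- NULL
    t_cursor <- 0
    add_rest <- function(dur) {
      n <- round(dur / dt)
      v_all <<- c(v_all, numeric(n)); w_all <<- c(w_all, numeric(n))
      t_cursor <<- t_cursor + n * dt
    }
    add_rest(lead_rest)
    bouts <- NULL
    for (b in seq_len(nrow(script))) {
      style <- script$style[[b]]
      active <- style$kind != "passive_attendant"
      # per-bout realization: cruise speed, oscillation depth, cadence and
      # steering jitter all vary between bouts, so the two classes overlap
      # rather than separating on any single parameter
      cruise <- max(0.28, style$mean_speed * script$speed_factor[b] *
                      exp(stats::rnorm(1, 0, 0.3)))
      osc <- min(0.4, max(0.01, style$speed_oscillation_fraction *
                            exp(stats::rnorm(1, 0, 0.5))))
      # minority modes make the task nonlinear: self-propellers sometimes
      # push once and coast; attendants sometimes stroll slowly over bumps
      mode <- "usual"
      u <- stats::runif(1)
      if (active && u < 0.12) {
        mode <- "coast"; osc <- osc * 0.25; cruise <- max(0.28, cruise * 0.85)
      } else if (!active && u < 0.12) {
        mode <- "stroll"; osc <- min(0.4, osc * 2.2)
        cruise <- max(0.28, cruise * 0.55)
      }
      f <- if (active) {
        style$push_frequency * exp(stats::rnorm(1, 0, 0.1))
      } else {
        stats::runif(1, 0.7, 1.1)   # attendant step cadence bleeding through
      }
      jit <- style$yaw_jitter_sd * exp(stats::rnorm(1, 0, 0.4)) *
        (if (mode == "stroll") 1.8 else 1)
      prof <- bout_speed_profile_(script$distance[b], cruise, dt)
      t <- prof$t; v <- prof$v
      n <- length(t)
      cyc <- floor(f * t)
      amp <- pmin(0.55, osc * (1 + 0.15 * stats::rnorm(max(cyc) + 1L)))[cyc + 1L]
      v <- v * (1 + amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi) * !active))
      if (script$kind[b] == "stop_go") {
        total <- t[n]
        env <- 1 - 0.97 * (exp(-((t - total / 3) / 0.35)^2) +
                           exp(-((t - 2 * total / 3) / 0.35)^2))
        v <- v * env
      }
      w <- smooth_jitter_(n, jit, dt)
      if (script$kind[b] == "slalom") {
        w <- w + 25 * sin(2 * pi * 0.3 * t)
      }
      if (script$bout[b] == "free_roam") {
        # free movement through the building: corridors, doorways, corners -
        # large slow steering excursions independent of propulsion type
        w <- w + smooth_jitter_(n, stats::runif(1, 5, 20), dt, tau = 1.5)
      }
      if (style$wobble_amp != 0) {
        w <- w + style$wobble_amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
      if (style$sway_amp != 0) {
        w <- w + style$sway_amp * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
      }
      v <- v * style$direction
      # taper yaw to zero while (nearly) stationary
      w <- w * pmin(1, abs(v) / 0.15)
      v_all <- c(v_all, v); w_all <- c(w_all, w)
      ann <- rbind(ann, data.frame(
        start = t_cursor, end = t_cursor + (n - 1L) * dt,
        label = if (active) "active" else "passive"))
      bouts <- rbind(bouts, data.frame(
        bout = script$bout[b], kind = script$kind[b],
        label = if (active) "active" else "passive",
        start = t_cursor, end = t_cursor + (n - 1L) * dt,
        cruise = cruise, osc = osc, freq = f, yaw_jitter = jit, mode = mode))
      t_cursor <- t_cursor + n * dt
      add_rest(script$rest_after[b])
    }
    n_tot <- length(v_all)
    out <- data.frame(time = (seq_len(n_tot) - 1L) * dt,
                      speed = v_all, yaw_rate = w_all, pitch_rate = 0)
    structure(out, annotations = ann, bouts = bouts,
              class = c("kinematic_series", "data.frame"))
  })
}

#' Render a ground-truth trajectory into raw IMU streams
#'
#' Inverts the kinematic model: the wheel-hub gyro x-axis carries the
#' wheel spin `v_wheel / r`, with `v_wheel = v + yaw * track/2` for the
#' right wheel; chair yaw projects onto the spinning y/z axes as
#' `gy = yaw * sin(theta)`, `gz = yaw * cos(theta)` with `theta` the
#' integrated wheel angle. The wheel accelerometer sees gravity rotated by
#' `theta` in its y-z plane plus the hub's tangential and centripetal
#' accelerations; the frame sensor (z up) sees the yaw rate on gyro z and
#' body-frame linear accelerations plus gravity. White noise and a
#' constant per-trial gyro bias are then added.
#'
#' @param truth Trajectory from [simulate_trajectory].
#' @param geometry A [wheelchair_geometry].
#' @param noise An [imu_noise]; use `imu_noise(0, 0, 0)` for noiseless
#'   oracle rendering.
#' @param seed Integer seed (noise and bias only).
#' @param frame_clock_offset Shift of the frame-sensor clock in seconds
#'   (default 0; the sensors are modelled as hardware-synchronized).
#' @return List with `wheel` and `frame` [imu_stream]s.
#' @export
render_imu <- function(truth, geometry, noise = imu_noise(), seed = 1L,
                       frame_clock_offset = 0) {
  stopifnot(inherits(geometry, "wheelchair_geometry"))
  t <- truth$time
  v <- truth$speed
  omega <- truth$yaw_rate            # deg/s
  omega_rad <- omega * DEG2RAD
  r <- geometry$wheel_diameter / 2
  s <- if (geometry$sensor_side == "right") 1 else -1
  v_wheel <- v + omega_rad * geometry$track_width / 2   # right-wheel rim speed
  gx <- s * v_wheel / r * RAD2DEG
  theta <- cumtrapz_(t, v_wheel / r * RAD2DEG)          # physical wheel angle, deg
  th <- theta * DEG2RAD
  gy <- omega * sin(th)
  gz <- omega * cos(th)
  n <- length(t)
  a_tan <- differentiate_raw_(v_wheel, t)
  a_lat <- -v * omega_rad
  ax <- a_lat
  ay <- a_tan * cos(th) + GRAVITY * sin(th)
  az <- -a_tan * sin(th) + GRAVITY * cos(th)
  f_ax <- a_lat
  f_ay <- differentiate_raw_(v, t)
  f_az <- rep(GRAVITY, n)
  local_seed_(child_seed_(seed, "render"), {
    add_noise <- function(g, a) {
      bias <- stats::runif(3, -noise$bias_range, noise$bias_range)
      g <- g + matrix(stats::rnorm(3 * n, sd = noise$gyro_sd), n, 3) +
        matrix(bias, n, 3, byrow = TRUE)
      a <- a + matrix(stats::rnorm(3 * n, sd = noise$accel_sd), n, 3)
      list(g = g, a = a)
    }
    wn <- add_noise(cbind(gx, gy, gz), cbind(ax, ay, az))
    fn <- add_noise(cbind(0, 0, omega), cbind(f_ax, f_ay, f_az))
    list(wheel = imu_stream(t, wn$g, wn$a, "wheel"),
         frame = imu_stream(t + frame_clock_offset, fn$g, fn$a, "frame"))
  })
}

# plain central difference of a smooth ground-truth series (no filtering)
#' @noRd
differentiate_raw_ <- function(x, t) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Simulate one complete trial for one participant
#'
#' Runs the four-bout protocol in the participant's own propulsion style,
#' repeats it attendant-pushed, then appends a free-roaming block of short
#' mixed active/passive bouts, and renders the whole trajectory into wheel
#' and frame sensor streams.
#'
#' @param participant_id Identifier.
#' @param diagnosis `"stroke"` or `"amputation"`.
#' @param active_style A [propulsion_style] for self-propulsion.
#' @param passive_style A [propulsion_style] for attendant pushing.
#' @param n_free Number of free-roaming bouts (default 27).
#' @param free_active_share Probability that a free bout is self-propelled
#'   (default 0.58).
#' @param geometry A [wheelchair_geometry].
#' @param noise An [imu_noise].
#' @param seed Integer seed.
#' @return A `simulated_trial`: list with `truth`, `wheel`, `frame`,
#'   `annotations` (an [annotation_track]), `participant_id`, `diagnosis`,
#'   `seed`.
#' @export
simulate_trial <- function(participant_id, diagnosis, active_style,
                           passive_style = propulsion_style("passive_attendant"),
                           n_free = 27L, free_active_share = 0.58,
                           geometry = wheelchair_geometry(),
                           noise = imu_noise(), seed = 1L) {
  script <- rbind(protocol_script(active_style),
                  protocol_script(passive_style))
  free <- local_seed_(child_seed_(seed, "free"), {
    k <- n_free
    act <- stats::runif(k) < free_active_share
    data.frame(bout = "free_roam",
               kind = "straight",
               distance = stats::runif(k, 5, 14),
               speed_factor = stats::runif(k, 0.85, 1.35),
               rest_after = stats::runif(k, 2, 4)) |>
      within(style <- I(lapply(act, function(a)
        if (a) active_style else passive_style)))
  })
  script <- rbind(script, free)
  truth <- simulate_trajectory(script, seed = seed)
  streams <- render_imu(truth, geometry, noise, seed = seed)
  track <- annotation_track(attr(truth, "annotations"),
                            participant_id = participant_id,
                            diagnosis = diagnosis,
                            propulsion_mode = active_style$kind)
  structure(list(truth = truth, wheel = streams$wheel, frame = streams$frame,
                 annotations = track, participant_id = participant_id,
                 diagnosis = diagnosis, seed = seed),
            class = "simulated_trial")
}

#' Generate a synthetic study cohort
#'
#' Emulates a 24-participant rehabilitation cohort: diagnoses split about
#' 11 stroke / 13 amputation; some stroke participants propel with one
#' hand and one foot, one amputee drives backward with the prosthetic
#' foot, the rest push bimanually. Self-propulsion cruise speed is drawn
#' around 0.56 m/s (stroke) or 0.68 m/s (amputation). With defaults the
#' cohort yields about 950 movement segments at a roughly 55/45
#' active/passive mix, mostly shorter than 20 s.
#'
#' `class_contrast` scales every active-vs-passive style difference; at 0
#' the active styles become parameter-identical to the attendant style
#' (labels kept), so classifier performance must fall to the base rate.
#'
#' @param n_participants Number of participants (default 24).
#' @param seed Integer root seed.
#' @param geometry A [wheelchair_geometry].
#' @param noise An [imu_noise].
#' @param class_contrast 1 = full style contrast (default), 0 = none.
#' @return List of `simulated_trial` objects (class `simulated_cohort`).
#' @export
generate_cohort <- function(n_participants = 24L, seed = 1L,
                            geometry = wheelchair_geometry(),
                            noise = imu_noise(), class_contrast = 1) {
  if (n_participants < 2L) stop("need at least 2 participants")
  passive <- propulsion_style("passive_attendant")
  blend <- function(a, p) p + class_contrast * (a - p)
  trials <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pseed <- child_seed_(seed, paste0("participant", i))
    setup <- local_seed_(pseed, {
      diagnosis <- if (i <= round(n_participants * 11 / 24)) "stroke" else "amputation"
      kind <- if (diagnosis == "stroke") {
        if (stats::runif(1) < 0.4) "active_one_hand_one_foot" else "active_bimanual"
      } else if (i == n_participants) {
        "active_backward_foot"   # the one backward driver
      } else {
        "active_bimanual"
      }
      base_v <- if (diagnosis == "stroke") 0.56 else 0.68
      v <- base_v * stats::rnorm(1, 1, 0.08)
      list(diagnosis = diagnosis, kind = kind, v = v,
           n_free = sample(25:29, 1))
    })
    ref <- propulsion_style(setup$kind)
    active <- propulsion_style(
      setup$kind,
      push_frequency = blend(ref$push_frequency, passive$push_frequency),
      speed_oscillation_fraction =
        blend(ref$speed_oscillation_fraction, passive$speed_oscillation_fraction),
      yaw_jitter_sd = blend(ref$yaw_jitter_sd, passive$yaw_jitter_sd),
      mean_speed = blend(setup$v, passive$mean_speed),
      wobble_amp = blend(ref$wobble_amp, passive$wobble_amp),
      sway_amp = blend(ref$sway_amp, passive$sway_amp),
      direction = if (class_contrast > 0) ref$direction else passive$direction)
    trials[[i]] <- simulate_trial(
      participant_id = sprintf("P%02d", i), diagnosis = setup$diagnosis,
      active_style = active, passive_style = passive,
      n_free = setup$n_free, geometry = geometry, noise = noise,
      seed = child_seed_(seed, paste0("trial", i)))
  }
  structure(trials, class = c("simulated_cohort", "list"))
}
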