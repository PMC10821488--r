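geom <- wheelchair_geometry()   # 0.6 m wheel, 0.56 m track, right side

test_that("gyro offset correction recovers an exact constant bias at rest", {
  s <- make_stationary_stream(500, bias = c(2, -1, 0.5))
  out <- correct_gyro_offset(s)
  expect_lt(max(abs(colMeans(out$gyro))), 1e-9)
  expect_equal(out$accel, s$accel)                 # accel untouched
})

test_that("streams with no stationary samples are returned unchanged with a warning", {
  s <- make_stationary_stream(100, bias = c(20, 0, 0))
  expect_warning(out <- correct_gyro_offset(s), "not corrected")
  expect_equal(out$gyro, s$gyro)
})

test_that("offset correction is idempotent", {
  tr <- noiseless_trial()
  biased <- tr$wheel
  biased$gyro <- sweep(biased$gyro, 2, c(-1.5, 0.8, 0.3), "+")
  once <- correct_gyro_offset(biased)
  twice <- correct_gyro_offset(once)
  expect_equal(twice$gyro, once$gyro, tolerance = 1e-6)
})

test_that("injected bias is recovered within 0.05 deg/s at 20% stationary time", {
  # one long bout bracketed by long rests: ~20% of samples stationary
  style <- propulsion_style("active_bimanual", yaw_jitter_sd = 0,
                            mean_speed = 0.7)
  script <- data.frame(bout = "normal_9m", kind = "straight", distance = 25,
                       speed_factor = 1, rest_after = 8)
  script$style <- I(list(style))
  tr <- simulate_trajectory(script, seed = 8, lead_rest = 8)
  streams <- render_imu(tr, geom, imu_noise(0.5, 0.05, 0), seed = 8)
  stationary_share <- mean(abs(tr$speed) < 1e-9)
  expect_gt(stationary_share, 0.15)
  bias <- c(1.5, 1.5, 1.5)
  biased <- streams$wheel
  biased$gyro <- sweep(biased$gyro, 2, bias, "+")
  corrected <- correct_gyro_offset(biased)
  recovered <- colMeans(biased$gyro - corrected$gyro)
  expect_lt(max(abs(recovered - bias)), 0.05)
})

test_that("wheel speed follows v = omega * r with forward sign", {
  s <- make_stationary_stream(3, bias = c(114.5916, 0, 0))  # 2 rad/s spin
  expect_equal(wheel_speed(s, geom), rep(0.6, 3), tolerance = 1e-6)
  expect_equal(wheel_speed(make_stationary_stream(3), geom), rep(0, 3))
  expect_error(wheel_speed(s, wheelchair_geometry(wheel_diameter = -1)),
               "wheel_diameter")
})

test_that("chair-center speed corrects wheel speed by yaw rate and track width", {
  expect_equal(chair_speed(1.0, 0, geom), 1.0)
  # right wheel, leftward (positive) yaw 0.5 rad/s, track 0.56 m
  expect_equal(chair_speed(1.0, 28.64789, geom), 1.0 - 0.5 * 0.28,
               tolerance = 1e-6)
  expect_error(chair_speed(c(1, 1), 0, geom), "equal length")
})

test_that("frame yaw rate is the vertical gyro axis; missing frame errors", {
  s <- make_stationary_stream(5, bias = c(0, 0, 30), role = "frame")
  expect_equal(yaw_rate_from_frame(s), rep(30, 5))
  expect_error(yaw_rate_from_frame(NULL), "S1")
})

test_that("wheel decomposition is exact at rest and on noiseless simulated motion", {
  rest <- make_stationary_stream(200)
  d <- decompose_wheel_gyro(rest)
  expect_equal(d$roll_rate, rep(0, 200))
  expect_lt(max(abs(d$yaw_rate)), 1e-9)
  expect_lt(max(abs(diff(d$wheel_angle))), 1e-9)

  # straight push: roll carries the spin, yaw stays near zero
  style <- propulsion_style("active_bimanual", yaw_jitter_sd = 0)
  script <- data.frame(bout = "normal_9m", kind = "straight", distance = 9,
                       speed_factor = 1, rest_after = 2)
  script$style <- I(list(style))
  tr <- simulate_trajectory(script, seed = 4)
  st <- render_imu(tr, geom, imu_noise(0, 0, 0), seed = 4)
  d <- decompose_wheel_gyro(st$wheel)
  expect_equal(d$roll_rate, st$wheel$gyro[, 1])
  expect_lt(rmse(d$yaw_rate, tr$yaw_rate), 0.5)
})

test_that("decomposition tracks a 1 Hz slalom yaw oscillation within 2 deg/s RMSE", {
  t <- seq(0, 30, by = 0.02)
  truth <- structure(
    data.frame(time = t, speed = rep(1, length(t)),
               yaw_rate = 20 * sin(2 * pi * 1 * t), pitch_rate = 0),
    class = c("kinematic_series", "data.frame"))
  st <- render_imu(truth, geom, imu_noise(0, 0, 0), seed = 1)
  d <- decompose_wheel_gyro(st$wheel)
  expect_lt(rmse(d$yaw_rate, truth$yaw_rate), 2)
})

test_that("a 360-degree pirouette integrates to 360 degrees of yaw", {
  t <- seq(0, 12, by = 0.02)
  truth <- structure(
    data.frame(time = t, speed = 0, yaw_rate = 30, pitch_rate = 0),
    class = c("kinematic_series", "data.frame"))
  st <- render_imu(truth, geom, imu_noise(0, 0, 0), seed = 1)
  yaw <- yaw_rate_from_frame(st$frame)
  total <- sum(diff(t) * (yaw[-1] + yaw[-length(yaw)]) / 2)
  expect_equal(total, 360, tolerance = 1)
})

test_that("differentiate matches closed forms and the filter response bound", {
  t <- seq(0, 10, by = 0.02)
  d <- differentiate(0.2 * t, t)
  expect_equal(d[10:490], rep(0.2, 481), tolerance = 1e-6)
  expect_equal(differentiate(rep(3, length(t)), t), rep(0, length(t)))
  # 1 Hz sine: derivative amplitude 2*pi*f*A within the 6 Hz filter attenuation
  x <- 0.5 * sin(2 * pi * 1 * t)
  d <- differentiate(x, t)
  amp <- max(abs(d[100:400]))
  expect_equal(amp, 2 * pi * 0.5, tolerance = 0.02 * 2 * pi * 0.5)
  expect_message(differentiate(c(1, 2, 3), c(0, 0.02, 0.04)), "warm-up")
})

test_that("path reconstruction: straight line, closed circle, and distance invariance", {
  n <- 501L
  t <- (0:(n - 1)) * 0.02
  straight <- structure(
    data.frame(time = t, speed = 1, accel = 0, roll_rate = 0, pitch_rate = 0,
               yaw_rate = 0, roll_accel = 0, pitch_accel = 0, yaw_accel = 0,
               wheel_angle = 0),
    class = c("kinematic_series", "data.frame"))
  p <- reconstruct_path(straight)
  expect_equal(p$x[n], 10, tolerance = 1e-9)
  expect_equal(p$y[n], 0)
  expect_equal(attr(p, "distance"), 10, tolerance = 1e-9)

  t <- seq(0, 20, by = 0.02)
  circle <- straight[1, ][rep(1, length(t)), ]
  circle$time <- t; circle$speed <- pi / 10; circle$yaw_rate <- 18
  circle <- structure(circle, class = c("kinematic_series", "data.frame"))
  pc <- reconstruct_path(circle)
  expect_lt(sqrt(pc$x[length(t)]^2 + pc$y[length(t)]^2), 1e-2)

  rev <- straight; rev$speed <- -rev$speed
  rev <- structure(rev, class = c("kinematic_series", "data.frame"))
  expect_equal(attr(reconstruct_path(rev), "distance"), 10, tolerance = 1e-9)
})

test_that("noiseless oracle: S2 and S1 reproduce ground-truth speed and yaw", {
  tr <- noiseless_trial()
  k2 <- suppressMessages(compute_kinematics(tr$wheel, tr$frame, geom, "S2"))
  k1 <- suppressMessages(compute_kinematics(tr$wheel, NULL, geom, "S1"))
  expect_lt(rmse(k2$speed, tr$truth$speed), 1e-3)
  expect_lt(rmse(k2$yaw_rate, tr$truth$yaw_rate), 0.1)
  expect_lt(rmse(k1$speed, tr$truth$speed), 1e-2)
  expect_lt(rmse(k1$yaw_rate, tr$truth$yaw_rate), 2)
  # path endpoint error below 1% of travelled distance
  p_true <- reconstruct_path(tr$truth)
  p_est <- reconstruct_path(k2)
  n <- nrow(p_true)
  err <- sqrt((p_est$x[n] - p_true$x[n])^2 + (p_est$y[n] - p_true$y[n])^2)
  expect_lt(err, 0.01 * attr(p_true, "distance"))
})

test_that("S1 and S2 yaw series agree under default sensor noise", {
  tr <- noiseless_trial()
  noisy <- render_imu(tr$truth, geom, imu_noise(), seed = 77)
  k2 <- suppressMessages(compute_kinematics(noisy$wheel, noisy$frame, geom, "S2"))
  k1 <- suppressMessages(compute_kinematics(noisy$wheel, NULL, geom, "S1"))
  expect_gt(stats::cor(k1$yaw_rate, k2$yaw_rate), 0.95)
})

test_that("requesting S2 without a frame stream is an error", {
  tr <- noiseless_trial()
  expect_error(compute_kinematics(tr$wheel, NULL, geom, "S2"), "frame")
})
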