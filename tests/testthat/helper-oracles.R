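# Shared fixtures and independent oracles used across test files.

# stationary stream of n samples with optional gyro bias (deg/s)
make_stationary_stream <- function(n = 200, bias = c(0, 0, 0),
                                   role = "wheel", g = 9.80665) {
  t <- (seq_len(n) - 1L) / 50
  gyro <- matrix(rep(bias, each = n), n, 3)
  accel <- cbind(rep(0, n), rep(0, n), rep(g, n))
  imu_stream(t, gyro, accel, role)
}

# brute-force segmentation oracle: scan every maximal run explicitly
brute_force_segments <- function(time, speed, threshold = 0.1, min_dur = 2) {
  moving <- abs(speed) > threshold
  out <- NULL
  i <- 1L
  n <- length(speed)
  while (i <= n) {
    if (moving[i]) {
      j <- i
      while (j < n && moving[j + 1L]) j <- j + 1L
      if (time[j] - time[i] >= min_dur) {
        out <- rbind(out, data.frame(first = i, last = j))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# brute-force greedy correlation-pruning oracle on a plain matrix
brute_force_prune <- function(X, threshold = 0.7) {
  cols <- colnames(X)
  cols <- cols[apply(X, 2, stats::sd) > 0]
  kept <- character(0)
  for (p in cols) {
    ok <- TRUE
    for (q in kept) {
      if (abs(stats::cor(X[, p], X[, q])) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, p)
  }
  kept
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# a small noiseless protocol trial shared by kinematics oracle tests
noiseless_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_trajectory(protocol_script(propulsion_style("active_bimanual")),
                                seed = 42)
      streams <- render_imu(tr, wheelchair_geometry(), imu_noise(0, 0, 0),
                            seed = 42)
      cache <<- list(truth = tr, wheel = streams$wheel, frame = streams$frame)
    }
    cache
  }
})

# a small default-noise cohort shared by module tests (not the acceptance one)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(6, seed = 11)
    cache
  }
})

small_features <- local({
  cache <- list()
  function(variant = "S1") {
    if (is.null(cache[[variant]])) {
      cache[[variant]] <<- suppressMessages(
        cohort_feature_matrix(small_cohort(), variant = variant))
    }
    cache[[variant]]
  }
})

# internal seed-derivation, re-exported for composition tests
child_seed_for_test <- function(seed, label) wheelmotion:::child_seed_(seed, label)
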