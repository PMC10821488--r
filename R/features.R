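# Segment-level predictor construction: the fixed 56-column feature schema
# (8 derived kinematic series + 6 raw gyro series, times 4 aggregates) and
# correlation-based pruning of multicollinear predictors.

# Canonical series order; with the four aggregates in AGGREGATE_NAMES order
# this fixes the 56 column names and hence pruning tie-breaks.
DERIVED_SERIES <- c("speedfft", "accel", "rollrate", "pitchrate", "yawrate",
                    "rollaccel", "pitchaccel", "yawaccel")
RAW_SERIES <- c("rawgx", "rawgy", "rawgz", "rawgxdot", "rawgydot", "rawgzdot")
AGGREGATE_NAMES <- c("median", "sd", "skew", "kurt")

#' Canonical predictor column names
#'
#' @return Character vector of the 56 predictor names in canonical order:
#'   derived block (FFT-of-speed, linear acceleration, roll/pitch/yaw
#'   angular velocity and acceleration) then raw gyro block, each crossed
#'   with the aggregates median, sd, skewness, excess kurtosis.
#' @export
feature_names <- function() {
  as.vector(t(outer(c(DERIVED_SERIES, RAW_SERIES), AGGREGATE_NAMES,
                    paste, sep = "_")))
}

#' The four aggregate summaries of a series
#'
#' Sample median; standard deviation with denominator n; moment skewness
#' `g1 = m3 / m2^1.5`; excess kurtosis `g2 = m4 / m2^2 - 3`. A constant
#' series yields `(c, 0, 0, 0)`.
#'
#' @param x Non-empty numeric series.
#' @return Named numeric vector `median`, `sd`, `skew`, `kurt`.
#' @export
aggregate_stats <- function(x) {
  if (!length(x)) stop("cannot aggregate an empty series")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(c(median = stats::median(x), sd = 0, skew = 0, kurt = 0))
  }
  c(median = stats::median(x),
    sd = sqrt(m2),
    skew = mean(d^3) / m2^1.5,
    kurt = mean(d^4) / m2^2 - 3)
}

#' One-sided FFT amplitude spectrum of a segment's speed series
#'
#' The mean is removed, then the discrete Fourier transform is taken and
#' converted to one-sided amplitudes `2 |X_k| / N` for bins k = 1 ..
#' floor(N/2) (DC excluded). Downstream, the spectrum is summarised by the
#' four aggregates so the predictor count does not depend on segment
#' length.
#'
#' @param v Numeric speed series (at least 2 samples).
#' @param sample_rate Sampling rate in Hz (used for the frequency axis).
#' @return Data frame with columns `freq` (Hz) and `amplitude`.
#' @export
fft_amplitudes <- function(v, sample_rate = 50) {
  n <- length(v)
  if (n < 2L) stop("segment too short for a spectrum")
  X <- stats::fft(v - mean(v))
  k <- seq_len(floor(n / 2))
  data.frame(freq = k * sample_rate / n,
             amplitude = 2 * Mod(X[k + 1L]) / n)
}

#' @noRd
segment_feature_row_ <- function(kin, raw, first, last) {
  idx <- first:last
  t <- kin$time[idx]
  fs <- 1 / stats::median(diff(t))
  series <- list(
    speedfft = fft_amplitudes(kin$speed[idx], fs)$amplitude,
    accel = kin$accel[idx],
    rollrate = kin$roll_rate[idx],
    pitchrate = kin$pitch_rate[idx],
    yawrate = kin$yaw_rate[idx],
    rollaccel = kin$roll_accel[idx],
    pitchaccel = kin$pitch_accel[idx],
    yawaccel = kin$yaw_accel[idx],
    rawgx = raw$gyro[idx, 1],
    rawgy = raw$gyro[idx, 2],
    rawgz = raw$gyro[idx, 3],
    rawgxdot = differentiate(raw$gyro[idx, 1], t),
    rawgydot = differentiate(raw$gyro[idx, 2], t),
    rawgzdot = differentiate(raw$gyro[idx, 3], t)
  )
  unlist(lapply(series, aggregate_stats), use.names = FALSE)
}

#' Build the 56-predictor feature matrix for a set of segments
#'
#' For each segment, the derived block (8 series x 4 aggregates) comes from
#' the kinematic series: the FFT amplitude spectrum of chair speed (the
#' speed series enters only through its spectrum), linear acceleration, and
#' angular velocity and acceleration about roll, pitch and yaw. The raw
#' block (6 series x 4 aggregates) comes from the configuration's own
#' sensor - the wheel sensor for S1, the frame sensor for S2 - as the three
#' raw gyro channels and their smoothed derivatives. Segments labelled
#' `"unknown"` are dropped.
#'
#' @param segments Labelled segment table from [label_segments].
#' @param kin `kinematic_series` computed with the matching variant.
#' @param raw [imu_stream] of the variant's sensor, on the same clock as
#'   `kin` (wheel for S1, frame for S2).
#' @param variant `"S1"` or `"S2"`.
#' @return A `feature_matrix`: data frame with the 56 predictor columns,
#'   `y` (1 = active, 0 = passive), `diagnosis` and `participant_id`;
#'   attribute `variant` and `predictors`.
#' @export
build_feature_matrix <- function(segments, kin, raw, variant = c("S1", "S2")) {
  variant <- match.arg(variant)
  stopifnot(inherits(kin, "kinematic_series"), inherits(raw, "imu_stream"))
  if (!is.null(attr(kin, "variant")) && attr(kin, "variant") != variant) {
    stop(sprintf("kinematics computed for %s but variant %s requested",
                 attr(kin, "variant"), variant))
  }
  expected_role <- if (variant == "S1") "wheel" else "frame"
  if (raw$sensor_role != expected_role) {
    stop(sprintf("variant %s needs the %s sensor as raw input, got %s",
                 variant, expected_role, raw$sensor_role))
  }
  if (length(raw) != nrow(kin)) {
    stop("raw stream and kinematic series must share a clock")
  }
  keep <- segments$label %in% c("active", "passive")
  segments <- segments[keep, , drop = FALSE]
  rows <- t(vapply(seq_len(nrow(segments)), function(i) {
    segment_feature_row_(kin, raw, segments$first[i], segments$last[i])
  }, numeric(56)))
  colnames(rows) <- feature_names()
  fm <- as.data.frame(rows)
  fm$y <- as.integer(segments$label == "active")
  fm$diagnosis <- if ("diagnosis" %in% names(segments)) segments$diagnosis else "stroke"
  fm$participant_id <- if ("participant_id" %in% names(segments)) segments$participant_id else "P0"
  if (anyNA(fm)) stop("feature matrix contains missing values")
  structure(fm, variant = variant, predictors = feature_names(),
            class = c("feature_matrix", "data.frame"))
}

#' Drop multicollinear predictors by greedy correlation pruning
#'
#' Zero-variance columns are removed first. The remaining predictors are
#' scanned in canonical column order; a column is dropped iff its absolute
#' Pearson correlation with any already-retained column strictly exceeds
#' `threshold`.
#'
#' @param fm A `feature_matrix` (at least 2 rows).
#' @param threshold Correlation magnitude above which a predictor is
#'   dropped (default 0.7).
#' @return Character vector of retained predictor names, in canonical
#'   order.
#' @export
prune_correlated <- function(fm, threshold = 0.7) {
  preds <- attr(fm, "predictors")
  if (is.null(preds)) preds <- setdiff(names(fm), c("y", "diagnosis", "participant_id"))
  if (nrow(fm) < 2L) stop("need at least 2 rows to estimate correlations")
  X <- as.matrix(fm[, preds, drop = FALSE])
  keep <- preds[apply(X, 2, stats::sd) > 0]
  retained <- character(0)
  for (p in keep) {
    if (!length(retained)) {
      retained <- p
      next
    }
    r <- abs(stats::cor(X[, p], X[, retained, drop = FALSE]))
    if (all(r <= threshold)) retained <- c(retained, p)
  }
  retained
}
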