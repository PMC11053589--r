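#' Minimum sampling rate for a band-limited motion signal
#'
#' Nyquist-Shannon: a signal whose highest component is `max_signal_hz`
#' needs at least twice that sampling rate.  Human gait stays below about
#' 2.5 Hz when walking and 4.5 Hz on stairs, so 9 Hz suffices and the
#' wearable's 20-50 Hz is comfortable.
#'
#' @param max_signal_hz Highest signal frequency, Hz.
#' @return Minimum sampling rate, Hz.
#' @export
nyquist_min_rate <- function(max_signal_hz) {
  stopifnot(.is_scalar_num(max_signal_hz), max_signal_hz > 0)
  2 * max_signal_hz
}

#' Stationary gyroscope bias self-calibration
#'
#' Estimates the constant gyroscope offset as the per-axis mean over a
#' window in which the sensor is verified to be stationary: the per-axis
#' gyro sample standard deviation must stay below `gyro_sd_max` and the
#' mean accelerometer norm must stay within `accel_dev_max` of gravity.
#'
#' @param stream An [imu_stream()].
#' @param window Either a scalar duration (seconds from the stream start) or
#'   a length-2 `c(t0, t1)` absolute window.
#' @param gyro_sd_max Stationarity threshold on the gyro sd, rad/s.
#' @param accel_dev_max Stationarity threshold on `| mean ||a|| - g |`, m/s^2.
#' @param min_samples Minimum number of samples required in the window.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return A `gyro_bias` object: `bias` (rad/s, length 3), `n_samples`, and
#'   `stationarity_score` (max ratio of the observed statistics to their
#'   thresholds; < 1 when comfortably stationary).
#' @export
calibrate_gyro_bias <- function(stream, window = NULL, gyro_sd_max = 0.02,
                                accel_dev_max = 0.3, min_samples = 50L,
                                gravity = 9.81) {
  stopifnot(inherits(stream, "imu_stream"))
  t <- stream$times
  if (is.null(window)) {
    keep <- rep(TRUE, length(t))
  } else if (length(window) == 1L) {
    keep <- t <= t[1] + window
  } else {
    keep <- t >= window[1] & t <= window[2]
  }
  n <- sum(keep)
  if (n < min_samples)
    stop(sprintf("calibration window holds %d samples; need >= %d", n, min_samples))
  g <- stream$angular_rate[keep, , drop = FALSE]
  a <- stream$specific_force[keep, , drop = FALSE]
  gyro_sd <- apply(g, 2, sd)
  if (any(gyro_sd > gyro_sd_max))
    stop_not_stationary(
      sprintf("gyro sd %.4f rad/s exceeds %.4f: sensor not stationary",
              max(gyro_sd), gyro_sd_max), check = "gyro_sd")
  accel_dev <- abs(mean(sqrt(rowSums(a^2))) - gravity)
  if (accel_dev > accel_dev_max)
    stop_not_stationary(
      sprintf("accelerometer norm deviates %.3f m/s^2 from g: sensor not stationary",
              accel_dev), check = "accel_norm")
  structure(list(bias = colMeans(g), n_samples = n,
                 stationarity_score = max(max(gyro_sd) / gyro_sd_max,
                                          accel_dev / accel_dev_max)),
            class = "gyro_bias")
}

#' Zero gyroscope bias
#'
#' Convenience constructor for running the observer without calibration.
#' @return A `gyro_bias` with zero components.
#' @export
zero_gyro_bias <- function() {
  structure(list(bias = c(0, 0, 0), n_samples = 0L, stationarity_score = 0),
            class = "gyro_bias")
}

#' Gravity-observer tuning parameters
#'
#' The observer tracks the unit gravity direction in the sensor frame with a
#' 3x3 covariance.  Between accelerometer updates the direction is rotated
#' by the bias-corrected gyro; accelerometer updates are hard-gated on the
#' deviation of the measured norm from g, because large deviations signal
#' dynamic (non-gravitational) acceleration.
#'
#' Defaults are set from the error budget rather than the sensor data
#' sheet: the process noise matches the angle random walk induced by the
#' gyro white noise (about 3e-4 rad/sqrt(s) at 0.005 rad/s and 50 Hz), and
#' the accelerometer "noise" is dominated not by the MEMS white noise but
#' by dynamic-acceleration contamination that a pure norm gate cannot
#' reject (a sample can pass the gate while its direction is tilted by
#' tens of degrees), hence the 4 m/s^2 default.  Together they give a
#' motion-phase correction time constant of several hundred seconds: long
#' runs stay drift-free while a one-minute recording is carried almost
#' entirely by the calibrated gyro.  The initial covariance is that of the
#' initializing measurement — [observer_init()] seeds the direction from a
#' resting accelerometer sample, accurate to a fraction of a degree — not
#' an uninformed prior; an inflated prior would carry excess accelerometer
#' trust from quiet standing into the subsequent motion.
#'
#' @param process_noise_sd Gyro-propagation random walk, rad/sqrt(s).
#' @param accel_meas_noise_sd Accelerometer measurement noise, m/s^2
#'   (converted internally to direction units by dividing by g).
#' @param accel_gate_threshold Gate on `| ||a|| - g |`, m/s^2; default
#'   0.05 g.  A norm gate of x g still admits samples whose direction is
#'   tilted by up to `asin(sqrt((1 + x)^2 - 1))` by perpendicular dynamic
#'   acceleration (~29 deg at 0.15 g, ~17 deg at 0.05 g), so the gate is
#'   kept tight; stationary samples deviate only by the accelerometer
#'   white noise (~0.05 m/s^2) and always pass.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param initial_covariance Initial direction covariance, rad^2.
#' @return An `observer_params` list.
#' @export
observer_params <- function(process_noise_sd = 3e-4,
                            accel_meas_noise_sd = 4,
                            accel_gate_threshold = 0.05 * 9.81,
                            gravity = 9.81, initial_covariance = 1e-4) {
  stopifnot(process_noise_sd > 0, accel_meas_noise_sd > 0,
            accel_gate_threshold > 0, gravity > 0, initial_covariance > 0)
  structure(list(process_noise_sd = process_noise_sd,
                 accel_meas_noise_sd = accel_meas_noise_sd,
                 accel_gate_threshold = accel_gate_threshold,
                 gravity = gravity, initial_covariance = initial_covariance),
            class = "observer_params")
}

## Rotation matrix for rotation vector phi (axis * angle), Rodrigues form.
.rot_from_vec <- function(phi) {
  th <- sqrt(sum(phi^2))
  if (th < 1e-12) return(diag(3))
  k <- phi / th
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)  # column-major: K %*% v == k x v
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Initialize the gravity observer
#'
#' The gravity direction is seeded from the first accelerometer sample via
#' the static specific-force convention (`a = -g_dir * g` at rest, so
#' `g_dir = -a / ||a||`), with an isotropic initial covariance.
#'
#' @param first_accel Length-3 specific force, m/s^2.
#' @param params An [observer_params()].
#' @param time Timestamp of the initializing sample, seconds.
#' @return A `gravity_observer_state`: unit `gravity_dir`, 3x3 `covariance`,
#'   and `time`.
#' @export
observer_init <- function(first_accel, params = observer_params(), time = 0) {
  stopifnot(length(first_accel) == 3L, all(is.finite(first_accel)))
  nrm <- sqrt(sum(first_accel^2))
  if (nrm <= 0) stop("cannot initialize from a zero-norm accelerometer sample")
  structure(list(gravity_dir = -first_accel / nrm,
                 covariance = diag(3) * params$initial_covariance,
                 time = time),
            class = "gravity_observer_state")
}

#' Advance the gravity observer by one IMU sample
#'
#' Predict: rotate the gravity direction by minus the bias-corrected angular
#' rate over the elapsed time (gravity is fixed in the world, so it rotates
#' opposite to the sensor), and inflate the covariance by process noise.
#' Update: if the accelerometer norm is within the gate of g, perform a
#' Kalman update toward the measured direction `-a/||a||`; otherwise skip
#' the update.  The direction is renormalized and the covariance
#' symmetrized after every step.
#'
#' @param state A `gravity_observer_state`.
#' @param time Sample timestamp, seconds (must exceed `state$time`).
#' @param accel Length-3 specific force, m/s^2.
#' @param gyro Length-3 angular rate, rad/s.
#' @param bias A `gyro_bias` (use [zero_gyro_bias()] if uncalibrated).
#' @param params An [observer_params()].
#' @return The updated `gravity_observer_state`.
#' @export
observer_step <- function(state, time, accel, gyro, bias = zero_gyro_bias(),
                          params = observer_params()) {
  dt <- time - state$time
  if (!is.finite(dt) || dt <= 0)
    stop("sample timestamps must be strictly increasing")
  g <- state$gravity_dir
  P <- state$covariance
  # ---- predict
  w <- gyro - bias$bias
  R <- .rot_from_vec(-w * dt)
  g <- as.vector(R %*% g)
  P <- R %*% P %*% t(R) + diag(3) * (params$process_noise_sd^2 * dt)
  # ---- gated accelerometer update
  an <- sqrt(sum(accel^2))
  if (abs(an - params$gravity) <= params$accel_gate_threshold && an > 0) {
    z <- -accel / an
    if (sum(z * g) > -0.999) {  # antipodal measurement: keep prediction
      r <- (params$accel_meas_noise_sd / params$gravity)^2
      S <- P + diag(3) * r
      K <- P %*% solve(S)
      g <- g + as.vector(K %*% (z - g))
      P <- (diag(3) - K) %*% P
    }
  }
  P <- (P + t(P)) / 2
  g <- g / sqrt(sum(g^2))
  structure(list(gravity_dir = g, covariance = P, time = time),
            class = "gravity_observer_state")
}

#' Sagittal inclination from an observer state
#'
#' Signed inclination of the sensor from the vertical, projected onto the
#' sagittal plane: `atan2(-g_x, -g_z)` under the package frame convention
#' (forward lean positive).  Result in (-pi, pi].
#'
#' @param state A `gravity_observer_state`.
#' @return Inclination in radians.
#' @export
inclination_from_state <- function(state) {
  g <- state$gravity_dir
  .wrap_angle(atan2(-g[1], -g[3]))
}

#' Run the gravity observer over a whole IMU stream
#'
#' Folds [observer_step()] over the stream, emitting one inclination value
#' per input sample.  The state is initialized from the first finite
#' accelerometer sample.  The gyro passed to each step is the trapezoidal
#' average of the previous and current samples, which makes the
#' propagation second-order accurate in the sampling interval.  Samples
#' with non-finite values leave the state unchanged (the previous
#' inclination is repeated) and are counted in a single warning; wireless
#' dropouts are expected and must not corrupt the estimate.
#'
#' @param stream An [imu_stream()].
#' @param params An [observer_params()].
#' @param bias A `gyro_bias`; pass [zero_gyro_bias()] explicitly to run
#'   uncalibrated.
#' @return An [angle_series()] of inclinations on the stream timestamps.
#' @export
run_observer <- function(stream, params = observer_params(),
                         bias = zero_gyro_bias()) {
  stopifnot(inherits(stream, "imu_stream"), inherits(bias, "gyro_bias"))
  n <- length(stream$times)
  if (n == 0L) return(angle_series(numeric(0), numeric(0), stream$sensor_id))
  incl <- numeric(n)
  acc <- stream$specific_force
  gyr <- stream$angular_rate
  state <- observer_init(acc[1, ], params, time = stream$times[1])
  incl[1] <- inclination_from_state(state)
  n_bad <- 0L
  g_prev <- gyr[1, ]
  if (any(!is.finite(g_prev))) g_prev <- c(0, 0, 0)
  if (n > 1L) for (i in 2:n) {
    ai <- acc[i, ]; gi <- gyr[i, ]
    if (any(!is.finite(ai)) || any(!is.finite(gi)) ||
        !is.finite(stream$times[i])) {
      n_bad <- n_bad + 1L
      incl[i] <- incl[i - 1L]
      next
    }
    state <- observer_step(state, stream$times[i], ai, (g_prev + gi) / 2,
                           bias, params)
    g_prev <- gi
    incl[i] <- inclination_from_state(state)
  }
  if (n_bad > 0L)
    warning(sprintf("skipped %d non-finite samples in stream '%s'",
                    n_bad, stream$sensor_id))
  angle_series(stream$times, incl, sensor_id = stream$sensor_id)
}

#' Round-trip a value through 32-bit float precision
#'
#' The firmware publishes inclination as a 32-bit float; this helper
#' reproduces that quantization exactly.
#'
#' @param x Numeric vector.
#' @return `x` after an IEEE-754 single-precision round trip.
#' @export
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}
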