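#' Pendulum simulation configuration
#'
#' Describes a damped free-swinging pendulum with a sensor mounted at
#' distance `length` from the pivot.  Dynamics: theta'' = -(g/L) sin(theta)
#' - damping * theta'.
#'
#' @param length Pivot-to-sensor-mount distance in metres (> 0).
#' @param initial_angle Initial angle from the vertical, radians.
#' @param initial_rate Initial angular rate, rad/s.
#' @param damping Viscous damping coefficient, 1/s (>= 0).
#' @param gravity Gravitational acceleration, m/s^2.
#' @param duration Simulated time, seconds (> 0).
#' @param solver_dt Dense output grid step, seconds.  The default 1 ms
#'   out-resolves the 220 Hz reference rate.
#' @return A `pendulum_config` list.
#' @export
pendulum_config <- function(length = 0.25, initial_angle = pi / 6,
                            initial_rate = 0, damping = 0.2, gravity = 9.81,
                            duration = 60, solver_dt = 1e-3) {
  stopifnot(.is_scalar_num(length), length > 0,
            .is_scalar_num(initial_angle), .is_scalar_num(initial_rate),
            .is_scalar_num(damping), damping >= 0,
            .is_scalar_num(gravity), gravity > 0,
            .is_scalar_num(duration), duration > 0,
            .is_scalar_num(solver_dt), solver_dt > 0, solver_dt <= duration)
  structure(list(length = length, initial_angle = initial_angle,
                 initial_rate = initial_rate, damping = damping,
                 gravity = gravity, duration = duration,
                 solver_dt = solver_dt),
            class = "pendulum_config")
}

.segment <- function(angle, rate, accel, pivot_accel) {
  list(angle = angle, rate = rate, accel = accel, pivot_accel = pivot_accel)
}

#' Ground-truth rigid-body motion trajectory
#'
#' Internal constructor for the dense ground-truth state produced by the
#' simulators: per-segment angle/rate/acceleration plus the world-frame
#' linear acceleration of each segment's pivot point.
#'
#' @param times Dense, strictly increasing time grid (s).
#' @param segments Named list; each element has fields `angle`, `rate`,
#'   `accel` (vectors, rad / rad/s / rad/s^2) and `pivot_accel`
#'   (n x 3 matrix, m/s^2, world frame).
#' @return An object of class `motion_trajectory`.
#' @export
motion_trajectory <- function(times, segments) {
  stopifnot(is.numeric(times), length(times) > 1L, all(diff(times) > 0))
  for (nm in names(segments)) {
    s <- segments[[nm]]
    stopifnot(length(s$angle) == length(times),
              length(s$rate) == length(times),
              length(s$accel) == length(times),
              nrow(s$pivot_accel) == length(times))
  }
  structure(list(times = times, segments = segments),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf("<motion_trajectory> %d points, %.3f s, segments: %s\n",
              length(x$times), max(x$times) - x$times[1],
              paste(names(x$segments), collapse = ", ")))
  invisible(x)
}

#' Simulate a damped free-swinging pendulum
#'
#' Integrates theta'' = -(g/L) sin(theta) - c theta' with classical RK4 on a
#' dense fixed grid.  The returned trajectory has two segments: `pendulum`
#' (the swinging arm) and `fixed` (a motionless vertical reference, angle 0),
#' mirroring a bench test with one fixed and one swinging sensor.
#'
#' @param config A [pendulum_config()].
#' @return A [motion_trajectory()].
#' @export
simulate_pendulum <- function(config) {
  stopifnot(inherits(config, "pendulum_config"))
  dt <- config$solver_dt
  n <- floor(config$duration / dt + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * dt
  gl <- config$gravity / config$length
  c0 <- config$damping
  th <- numeric(n); om <- numeric(n)
  th[1] <- config$initial_angle
  om[1] <- config$initial_rate
  f_om <- function(theta, omega) -gl * sin(theta) - c0 * omega
  for (i in seq_len(n - 1L)) {
    t1 <- th[i]; o1 <- om[i]
    k1t <- o1;              k1o <- f_om(t1, o1)
    k2t <- o1 + 0.5 * dt * k1o; k2o <- f_om(t1 + 0.5 * dt * k1t, k2t)
    k3t <- o1 + 0.5 * dt * k2o; k3o <- f_om(t1 + 0.5 * dt * k2t, k3t)
    k4t <- o1 + dt * k3o;       k4o <- f_om(t1 + dt * k3t, k4t)
    th[i + 1L] <- t1 + dt / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    om[i + 1L] <- o1 + dt / 6 * (k1o + 2 * k2o + 2 * k3o + k4o)
    if (!is.finite(th[i + 1L]) || !is.finite(om[i + 1L]))
      stop(sprintf("pendulum integration diverged at t = %.4f s", times[i + 1L]))
  }
  al <- f_om(th, om)
  zero3 <- matrix(0, n, 3)
  zero <- numeric(n)
  motion_trajectory(times, list(
    pendulum = .segment(th, om, al, zero3),
    fixed = .segment(zero, zero, zero, zero3)))
}

#' Mechanical energy of a pendulum trajectory
#'
#' Per-unit-mass energy 0.5 L^2 theta'^2 + g L (1 - cos theta) evaluated on
#' the dense grid; constant for an undamped pendulum.
#'
#' @param traj A trajectory from [simulate_pendulum()].
#' @param config The [pendulum_config()] that produced it.
#' @return Numeric vector of energies (J/kg) on the trajectory grid.
#' @export
pendulum_energy <- function(traj, config) {
  s <- traj$segments$pendulum
  0.5 * config$length^2 * s$rate^2 +
    config$gravity * config$length * (1 - cos(s$angle))
}

#' Treadmill gait configuration
#'
#' Parameterises a periodic sagittal-plane gait: a sinusoidal thigh
#' inclination and a knee-flexion profile built per stride from a smooth
#' normative shape (small stance-phase flexion bump, large swing-phase peak)
#' truncated to at most six Fourier harmonics.  Defaults follow normative
#' treadmill kinematics: swing flexion peaks near 65 deg when walking and
#' near 85 deg when jogging, and stride frequency rises from 0.9 Hz at
#' 3 km/h to 1.5 Hz at 12 km/h (step frequency double that, inside the
#' typical 1.5-2.5 Hz walking band).
#'
#' @param speed Belt speed in km/h (> 0).
#' @param duration Seconds of gait (>= one stride period).
#' @param cadence Stride frequency in Hz; default 0.9 + 0.2 (speed - 3)/3.
#' @param peak_swing_flexion Swing-phase knee flexion peak, degrees; default
#'   65 up to 9 km/h rising linearly to 85 at 12 km/h.
#' @param thigh_amplitude Thigh inclination amplitude, degrees.
#' @param stance_flexion Stance-phase knee flexion bump amplitude, degrees.
#' @param baseline_flexion Resting knee flexion between bumps, degrees.
#' @param thigh_length Hip-to-knee distance in metres (used to propagate the
#'   knee-joint linear acceleration to the shank sensor).
#' @param bounce_accel Vertical hip acceleration amplitude in m/s^2
#'   emulating flight-phase bounce; default 0 when walking (< 10 km/h) and
#'   3 m/s^2 when jogging.
#' @param n_harmonics Fourier harmonics retained for the knee profile (<= 6).
#' @param solver_dt Dense output grid step, seconds.
#' @param seed Optional integer recorded for provenance (the trajectory
#'   itself is deterministic; randomness enters via [imu_noise_model()]).
#' @return A `gait_config` list.
#' @export
gait_config <- function(speed, duration = 60, cadence = NULL,
                        peak_swing_flexion = NULL, thigh_amplitude = 25,
                        stance_flexion = 15, baseline_flexion = 2,
                        thigh_length = 0.45, bounce_accel = NULL,
                        n_harmonics = 6, solver_dt = 1e-3, seed = NULL) {
  stopifnot(.is_scalar_num(speed), speed > 0,
            .is_scalar_num(duration), duration > 0)
  if (is.null(cadence)) cadence <- max(0.5, 0.9 + 0.2 * (speed - 3) / 3)
  stopifnot(.is_scalar_num(cadence), cadence > 0)
  if (duration < 1 / cadence)
    stop("`duration` must cover at least one full stride period")
  if (is.null(peak_swing_flexion)) {
    peak_swing_flexion <-
      if (speed <= 9) 65 else 65 + min(1, (speed - 9) / 3) * 20
  }
  if (is.null(bounce_accel)) bounce_accel <- if (speed >= 10) 3 else 0
  stopifnot(n_harmonics >= 1, n_harmonics <= 6)
  structure(list(speed = speed, duration = duration, cadence = cadence,
                 peak_swing_flexion = peak_swing_flexion,
                 thigh_amplitude = thigh_amplitude,
                 stance_flexion = stance_flexion,
                 baseline_flexion = baseline_flexion,
                 thigh_length = thigh_length, bounce_accel = bounce_accel,
                 n_harmonics = n_harmonics, solver_dt = solver_dt,
                 seed = seed),
            class = "gait_config")
}

## Periodic raised-cosine bump centred at c0 with half-width w, on phase
## u in [0, 1).
.raised_cos <- function(u, c0, w) {
  d <- ((u - c0 + 0.5) %% 1) - 0.5
  ifelse(abs(d) < w, 0.5 * (1 + cos(pi * d / w)), 0)
}

## Fit the knee stride profile with a truncated Fourier series and return
## closures for the profile and its first two phase derivatives (degrees,
## degrees/phase, degrees/phase^2).
.knee_fourier <- function(config) {
  K <- config$n_harmonics
  u <- seq(0, 1, length.out = 721)[-721]
  base <- config$baseline_flexion +
    config$stance_flexion * .raised_cos(u, 0.15, 0.12) +
    (config$peak_swing_flexion - config$baseline_flexion) *
      .raised_cos(u, 0.72, 0.15)
  X <- cbind(1, do.call(cbind, lapply(seq_len(K), function(k)
    cbind(cos(2 * pi * k * u), sin(2 * pi * k * u)))))
  beta <- qr.solve(X, base)
  a0 <- beta[1]
  a <- beta[1 + 2 * seq_len(K) - 1]
  b <- beta[1 + 2 * seq_len(K)]
  eval_k <- function(uu, deriv = 0) {
    out <- if (deriv == 0) rep(a0, length(uu)) else numeric(length(uu))
    for (k in seq_len(K)) {
      wk <- 2 * pi * k
      out <- out + switch(as.character(deriv),
        "0" = a[k] * cos(wk * uu) + b[k] * sin(wk * uu),
        "1" = wk * (-a[k] * sin(wk * uu) + b[k] * cos(wk * uu)),
        "2" = wk^2 * (-a[k] * cos(wk * uu) - b[k] * sin(wk * uu)))
    }
    out
  }
  eval_k
}

## Thigh/knee/shank angle profiles and derivatives at absolute times t (s),
## optionally amplitude-modulated by a C2 window w(t) (with derivatives),
## used to ramp smoothly out of quiet standing.  Returns radians.
.gait_kinematics <- function(config, t, w = NULL, dw = NULL, d2w = NULL) {
  f <- config$cadence
  u <- f * t
  knee_fun <- .knee_fourier(config)
  At <- .deg2rad(config$thigh_amplitude)
  th <- At * sin(2 * pi * u)
  th1 <- At * 2 * pi * f * cos(2 * pi * u)
  th2 <- -At * (2 * pi * f)^2 * sin(2 * pi * u)
  kn <- .deg2rad(knee_fun(u, 0))
  kn1 <- .deg2rad(knee_fun(u, 1)) * f
  kn2 <- .deg2rad(knee_fun(u, 2)) * f^2
  if (!is.null(w)) {
    # product rule for the windowed profiles w(t) * theta(t)
    th2 <- d2w * th + 2 * dw * th1 + w * th2
    th1 <- dw * th + w * th1
    th <- w * th
    kn2 <- d2w * kn + 2 * dw * kn1 + w * kn2
    kn1 <- dw * kn + w * kn1
    kn <- w * kn
  }
  list(thigh = list(a = th, r = th1, acc = th2),
       knee = list(a = kn, r = kn1, acc = kn2),
       shank = list(a = th - kn, r = th1 - kn1, acc = th2 - kn2),
       u = u)
}

## World-frame linear acceleration of the knee joint given hip acceleration
## and the thigh state (distal end of a rotating segment).
.joint_point_accel <- function(hip_acc, L, th, th1, th2) {
  hip_acc + L * cbind(th2 * cos(th) - th1^2 * sin(th),
                      0,
                      th2 * sin(th) + th1^2 * cos(th))
}

#' Simulate periodic treadmill gait
#'
#' Produces a strictly periodic thigh/shank/knee trajectory on a dense grid.
#' Segments: `thigh` (pivot = hip, whose vertical bounce acceleration is
#' `bounce_accel`-scaled), `shank` (pivot = knee joint, with the propagated
#' hip + thigh acceleration), and `knee` (the joint angle itself, the
#' ground-truth signal for verification).
#'
#' @param config A [gait_config()].
#' @return A [motion_trajectory()].
#' @export
simulate_gait <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  dt <- config$solver_dt
  n <- floor(config$duration / dt + 1e-9) + 1L
  t <- (seq_len(n) - 1L) * dt
  kin <- .gait_kinematics(config, t)
  f <- config$cadence
  hip_acc <- cbind(0, 0, config$bounce_accel * sin(2 * pi * (2 * f) * t))
  knee_acc <- .joint_point_accel(hip_acc, config$thigh_length,
                                 kin$thigh$a, kin$thigh$r, kin$thigh$acc)
  zero3 <- matrix(0, n, 3)
  motion_trajectory(t, list(
    thigh = .segment(kin$thigh$a, kin$thigh$r, kin$thigh$acc, hip_acc),
    shank = .segment(kin$shank$a, kin$shank$r, kin$shank$acc, knee_acc),
    knee = .segment(kin$knee$a, kin$knee$r, kin$knee$acc, zero3)))
}

#' IMU sensor noise and saturation model
#'
#' Consumer-MEMS-like defaults: white accelerometer noise 0.05 m/s^2, white
#' gyroscope noise 0.005 rad/s, a constant per-axis gyro bias drawn
#' uniformly in +/-0.02 rad/s from `seed` (unless given), full scales
#' +/-16 g and +/-2000 dps.
#'
#' @param accel_noise_sd Accelerometer white noise sd, m/s^2.
#' @param gyro_noise_sd Gyroscope white noise sd, rad/s.
#' @param gyro_bias Length-3 constant bias (rad/s) or `NULL` to draw one.
#' @param gyro_bias_range Half-range for the drawn bias, rad/s.
#' @param accel_full_scale Accelerometer saturation, m/s^2.
#' @param gyro_full_scale Gyroscope saturation, rad/s.
#' @param seed Integer seed controlling the bias draw and the sample noise.
#' @return An `imu_noise_model` list (with the realised `gyro_bias`).
#' @export
imu_noise_model <- function(accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                            gyro_bias = NULL, gyro_bias_range = 0.02,
                            accel_full_scale = 16 * 9.81,
                            gyro_full_scale = 2000 * pi / 180,
                            seed = NULL) {
  stopifnot(accel_noise_sd >= 0, gyro_noise_sd >= 0,
            accel_full_scale > 0, gyro_full_scale > 0)
  if (is.null(gyro_bias)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    gyro_bias <- runif(3, -gyro_bias_range, gyro_bias_range)
  }
  stopifnot(length(gyro_bias) == 3L, all(is.finite(gyro_bias)))
  structure(list(accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
                 accel_full_scale = accel_full_scale,
                 gyro_full_scale = gyro_full_scale, seed = seed),
            class = "imu_noise_model")
}

.interp_traj <- function(times, y, ts) approx(times, y, ts)$y

#' Synthesize an IMU stream from a ground-truth trajectory
#'
#' Samples one segment of a trajectory at the wearable rate and applies the
#' measurement model: the gyroscope reads the body angular rate about the
#' sensor y-axis (`-theta'` under the package frame convention) plus bias
#' and white noise; the accelerometer reads the specific force at the mount
#' point, i.e. gravity plus the tangential (`r theta''`), centripetal
#' (`r theta'^2`) and pivot linear accelerations rotated into the sensor
#' frame, plus white noise.  Both channels saturate at the configured full
#' scales.
#'
#' @param traj A [motion_trajectory()].
#' @param segment Segment name in `traj$segments`.
#' @param mount_radius Pivot-to-sensor distance along the segment, metres.
#' @param rate Sampling rate, Hz.
#' @param noise An [imu_noise_model()].
#' @param sensor_id Label for the stream; defaults to the segment name.
#' @param time_offset Constant added to the emitted timestamps (clock skew).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return An [imu_stream()].
#' @export
imu_from_trajectory <- function(traj, segment, mount_radius, rate,
                                noise = imu_noise_model(),
                                sensor_id = segment, time_offset = 0,
                                gravity = 9.81) {
  stopifnot(inherits(traj, "motion_trajectory"),
            .is_scalar_num(rate), rate > 0,
            .is_scalar_num(mount_radius), mount_radius >= 0)
  if (!segment %in% names(traj$segments))
    stop(sprintf("unknown segment '%s'; available: %s", segment,
                 paste(names(traj$segments), collapse = ", ")))
  s <- traj$segments[[segment]]
  tt <- traj$times
  ts <- seq(tt[1], tt[length(tt)], by = 1 / rate)
  th <- .interp_traj(tt, s$angle, ts)
  om <- .interp_traj(tt, s$rate, ts)
  al <- .interp_traj(tt, s$accel, ts)
  px <- .interp_traj(tt, s$pivot_accel[, 1], ts)
  py <- .interp_traj(tt, s$pivot_accel[, 2], ts)
  pz <- .interp_traj(tt, s$pivot_accel[, 3], ts)
  r <- mount_radius
  # specific force in the sensor frame (see frame convention note)
  ax <- r * al + gravity * sin(th) + cos(th) * px + sin(th) * pz
  ay <- py
  az <- r * om^2 + gravity * cos(th) - sin(th) * px + cos(th) * pz
  n <- length(ts)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  acc <- cbind(ax, ay, az) +
    matrix(rnorm(3L * n, sd = noise$accel_noise_sd), n, 3)
  gyr <- cbind(0, -om, 0) +
    matrix(rep(noise$gyro_bias, each = n), n, 3) +
    matrix(rnorm(3L * n, sd = noise$gyro_noise_sd), n, 3)
  acc <- pmin(pmax(acc, -noise$accel_full_scale), noise$accel_full_scale)
  gyr <- pmin(pmax(gyr, -noise$gyro_full_scale), noise$gyro_full_scale)
  imu_stream(sensor_id, ts + time_offset, acc, gyr, rate,
             accel_full_scale = noise$accel_full_scale,
             gyro_full_scale = noise$gyro_full_scale)
}

#' Noiseless reference angle series
#'
#' Samples the ground-truth angle of a trajectory at a high reference rate
#' (default 220 Hz), standing in for an optical motion-analysis reference.
#' For gait trajectories the `knee` segment is used by default; otherwise
#' the first segment.
#'
#' @param traj A [motion_trajectory()].
#' @param rate Reference sampling rate, Hz.
#' @param segment Segment to sample; default `knee` if present, else the
#'   first segment.
#' @return An [angle_series()].
#' @export
reference_angle <- function(traj, rate = 220, segment = NULL) {
  stopifnot(inherits(traj, "motion_trajectory"), .is_scalar_num(rate), rate > 0)
  if (is.null(segment))
    segment <- if ("knee" %in% names(traj$segments)) "knee"
               else names(traj$segments)[1]
  s <- traj$segments[[segment]]
  tt <- traj$times
  ts <- seq(tt[1], tt[length(tt)], by = 1 / rate)
  angle_series(ts, .interp_traj(tt, s$angle, ts), sensor_id = segment)
}
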