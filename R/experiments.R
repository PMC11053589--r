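## End-to-end verification experiments: simulate -> noisy IMU streams ->
## calibrate -> fuse -> (joint) angle -> align/resample -> agreement stats.
## A stationary pre-roll is prepended to every run so the gyro bias can be
## self-calibrated exactly as the firmware would, and the wearable clock is
## skewed against the reference clock to exercise the alignment step.

.derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 10 + k) %% .Machine$integer.max)
}

## C2 smoothstep window rising 0 -> 1 over [t0, t0 + ramp], with first and
## second derivatives (needed to keep trajectory accelerations consistent).
.smoothstep <- function(t, t0, ramp) {
  s <- pmin(pmax((t - t0) / ramp, 0), 1)
  w <- 6 * s^5 - 15 * s^4 + 10 * s^3
  dw <- (30 * s^4 - 60 * s^3 + 30 * s^2) / ramp
  d2w <- (120 * s^3 - 180 * s^2 + 60 * s) / ramp^2
  inside <- t > t0 & t < t0 + ramp
  dw[!inside] <- 0; d2w[!inside] <- 0
  list(w = w, dw = dw, d2w = d2w)
}

## Pendulum trajectory with a quiet hold phase (theta = initial angle,
## zero rate) of `preroll` seconds prepended for self-calibration.
.pendulum_with_preroll <- function(config, preroll) {
  traj <- simulate_pendulum(config)
  dt <- config$solver_dt
  n0 <- floor(preroll / dt + 1e-9)
  t_hold <- (seq_len(n0) - 1L) * dt
  times <- c(t_hold, traj$times + preroll)
  hold <- rep(config$initial_angle, n0)
  zeros <- numeric(n0)
  z3 <- matrix(0, length(times), 3)
  p <- traj$segments$pendulum
  nall <- length(times)
  motion_trajectory(times, list(
    pendulum = .segment(c(hold, p$angle), c(zeros, p$rate),
                        c(zeros, p$accel), z3),
    fixed = .segment(numeric(nall), numeric(nall), numeric(nall), z3)))
}

#' Recording-session trajectories with a stationary pre-roll
#'
#' Real recordings start with the sensors at rest so the gyro bias can be
#' self-calibrated.  These builders prepend a quiet hold to the pendulum
#' trajectory (held at the release angle), or quiet standing plus a smooth
#' amplitude ramp to the gait trajectory.
#'
#' @param config A [pendulum_config()] or [gait_config()].
#' @param preroll Stationary seconds before the motion starts.
#' @param ramp Seconds over which gait amplitude ramps up from standing.
#' @return A [motion_trajectory()] whose motion begins at `t = preroll`.
#' @export
pendulum_session <- function(config, preroll = 5) {
  stopifnot(inherits(config, "pendulum_config"), preroll > 0)
  .pendulum_with_preroll(config, preroll)
}

#' @rdname pendulum_session
#' @export
gait_session <- function(config, preroll = 5, ramp = 1) {
  stopifnot(inherits(config, "gait_config"), preroll > 0, ramp > 0)
  .gait_with_preroll(config, preroll, ramp)
}

#' Pendulum verification experiment
#'
#' Reproduces the bench verification of the gravity observer: a damped
#' pendulum carries one sensor at its tip while a second sensor sits on a
#' fixed vertical axis; the measured angle is the difference of the two
#' estimated inclinations and is compared against the noiseless high-rate
#' ground truth.  A `preroll`-second stationary hold is prepended and used
#' for gyro self-calibration; the wearable streams run on a clock skewed by
#' `clock_skew` seconds, which the alignment step must recover.
#'
#' @param duration Swing duration, seconds.
#' @param length Pivot-to-sensor distance, metres.
#' @param initial_angle Release angle, radians.
#' @param damping Viscous damping, 1/s.
#' @param wearable_rate,reference_rate Sampling rates, Hz.
#' @param accel_noise_sd,gyro_noise_sd,gyro_bias_range Sensor noise model
#'   (see [imu_noise_model()]); set the first two to 0 and
#'   `gyro_bias_range = 0` for a noiseless run.
#' @param observer An [observer_params()].
#' @param seed Integer seed; per-sensor noise seeds are derived from it.
#' @param preroll Stationary hold for calibration, seconds.
#' @param clock_skew Wearable-vs-reference clock offset, seconds.
#' @param settle Seconds after the pre-roll excluded from scoring while the
#'   observer converges.
#' @param max_lag Alignment search half-width, seconds.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param traj Optional precomputed [simulate_pendulum()] trajectory for
#'   the same configuration (reused across seeds to save time).
#' @return A list: `stats` ([agreement_stats()]), `offset` (estimated clock
#'   offset, s), `bias` (per-sensor calibrated biases), `config` echo, and
#'   `files` (artifact paths, if written).
#' @export
run_pendulum_experiment <- function(duration = 60, length = 0.25,
                                    initial_angle = pi / 6, damping = 0.2,
                                    wearable_rate = 50, reference_rate = 220,
                                    accel_noise_sd = 0.05,
                                    gyro_noise_sd = 0.005,
                                    gyro_bias_range = 0.02,
                                    observer = observer_params(), seed = 1,
                                    preroll = 5, clock_skew = 0.2,
                                    settle = 1, max_lag = 2, out_dir = NULL,
                                    traj = NULL) {
  cfg <- pendulum_config(length = length, initial_angle = initial_angle,
                         damping = damping, duration = duration)
  if (is.null(traj)) traj <- simulate_pendulum(cfg)
  full <- .pendulum_with_preroll(cfg, preroll)
  mk_noise <- function(k) imu_noise_model(
    accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
    gyro_bias_range = gyro_bias_range, seed = .derive_seed(seed, k))
  swing <- imu_from_trajectory(full, "pendulum", mount_radius = length,
                               rate = wearable_rate, noise = mk_noise(1),
                               sensor_id = "swing", time_offset = clock_skew)
  fixed <- imu_from_trajectory(full, "fixed", mount_radius = 0,
                               rate = wearable_rate, noise = mk_noise(2),
                               sensor_id = "fixed", time_offset = clock_skew)
  bias_s <- calibrate_gyro_bias(swing, window = preroll - 0.5)
  bias_f <- calibrate_gyro_bias(fixed, window = preroll - 0.5)
  incl_s <- run_observer(swing, observer, bias_s)
  incl_f <- run_observer(fixed, observer, bias_f)
  est <- knee_angle(incl_s, incl_f)  # angle between the two sensors
  est <- window_series(est, from = clock_skew + preroll + settle)
  ref <- window_series(reference_angle(full, reference_rate,
                                       segment = "pendulum"),
                       from = preroll + settle)
  stats <- verify_agreement(est, ref, max_lag = max_lag)
  config_echo <- list(experiment = "pendulum", duration = duration,
                      length = length, initial_angle = initial_angle,
                      damping = damping, wearable_rate = wearable_rate,
                      reference_rate = reference_rate,
                      accel_noise_sd = accel_noise_sd,
                      gyro_noise_sd = gyro_noise_sd,
                      gyro_bias_range = gyro_bias_range, seed = seed,
                      preroll = preroll, clock_skew = clock_skew,
                      settle = settle, max_lag = max_lag,
                      observer = unclass(observer))
  files <- NULL
  if (!is.null(out_dir))
    files <- .write_experiment_artifacts(out_dir, "pendulum", config_echo,
                                         list(pendulum = stats),
                                         list(swing = swing, fixed = fixed),
                                         list(estimate = est, reference = ref))
  list(stats = stats, offset = attr(stats, "offset"),
       bias = list(swing = bias_s, fixed = bias_f),
       config = config_echo, files = files)
}

## Gait trajectory with quiet standing for `preroll` seconds, then a C2
## amplitude ramp into the periodic gait over `ramp` seconds.
.gait_with_preroll <- function(config, preroll, ramp = 1) {
  dt <- config$solver_dt
  n <- floor((preroll + config$duration) / dt + 1e-9) + 1L
  t <- (seq_len(n) - 1L) * dt
  wfun <- .smoothstep(t, preroll, ramp)
  kin <- .gait_kinematics(config, t - preroll, wfun$w, wfun$dw, wfun$d2w)
  f <- config$cadence
  hip_acc <- cbind(0, 0, wfun$w * config$bounce_accel *
                          sin(2 * pi * (2 * f) * (t - preroll)))
  knee_acc <- .joint_point_accel(hip_acc, config$thigh_length,
                                 kin$thigh$a, kin$thigh$r, kin$thigh$acc)
  z3 <- matrix(0, n, 3)
  motion_trajectory(t, list(
    thigh = .segment(kin$thigh$a, kin$thigh$r, kin$thigh$acc, hip_acc),
    shank = .segment(kin$shank$a, kin$shank$r, kin$shank$acc, knee_acc),
    knee = .segment(kin$knee$a, kin$knee$r, kin$knee$acc, z3)))
}

#' Treadmill gait verification experiment
#'
#' For each requested speed: simulate periodic gait, synthesize noisy thigh
#' and shank streams (50 Hz by default), self-calibrate on the standing
#' pre-roll, run the gravity observer on both streams, form the knee angle
#' as the inclination difference, then align, resample onto the wearable
#' clock and score against the noiseless high-rate ground-truth knee angle.
#'
#' @param speeds Belt speeds in km/h.
#' @param duration Gait duration per speed, seconds.
#' @param wearable_rate,reference_rate Sampling rates, Hz.
#' @param thigh_mount,shank_mount Pivot-to-sensor distances (hip->thigh
#'   sensor, knee->shank sensor), metres.
#' @param accel_noise_sd,gyro_noise_sd,gyro_bias_range Sensor noise model.
#' @param observer An [observer_params()].
#' @param seed Integer seed; per-speed, per-sensor seeds are derived.
#' @param preroll Quiet standing before walking, seconds.
#' @param ramp Seconds over which gait amplitude ramps up from standing.
#' @param clock_skew Wearable-vs-reference clock offset, seconds.
#' @param settle Seconds after the ramp excluded from scoring.
#' @param max_lag Alignment search half-width, seconds.
#' @param out_dir Optional directory for artifacts.
#' @param gait_options Named list of extra [gait_config()] arguments.
#' @return A list: `per_speed` (named list of [agreement_stats()]),
#'   `table` (one row per speed: rmse, std_dev, mean_diff, mean_abs_diff,
#'   min_diff, max_diff, n), `config` echo and `files`.
#' @export
run_gait_experiment <- function(speeds = c(3, 6, 9, 12), duration = 60,
                                wearable_rate = 50, reference_rate = 220,
                                thigh_mount = 0.25, shank_mount = 0.20,
                                accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                                gyro_bias_range = 0.02,
                                observer = observer_params(), seed = 1,
                                preroll = 5, ramp = 1, clock_skew = 0.2,
                                settle = 1, max_lag = 2, out_dir = NULL,
                                gait_options = list()) {
  stopifnot(all(speeds > 0))
  per_speed <- list()
  for (i in seq_along(speeds)) {
    sp <- speeds[i]
    cfg <- do.call(gait_config, c(list(speed = sp, duration = duration),
                                  gait_options))
    full <- .gait_with_preroll(cfg, preroll, ramp)
    mk_noise <- function(k) imu_noise_model(
      accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
      gyro_bias_range = gyro_bias_range,
      seed = .derive_seed(seed, 10 * i + k))
    thigh <- imu_from_trajectory(full, "thigh", mount_radius = thigh_mount,
                                 rate = wearable_rate, noise = mk_noise(1),
                                 sensor_id = "thigh", time_offset = clock_skew)
    shank <- imu_from_trajectory(full, "shank", mount_radius = shank_mount,
                                 rate = wearable_rate, noise = mk_noise(2),
                                 sensor_id = "shank", time_offset = clock_skew)
    bias_t <- calibrate_gyro_bias(thigh, window = preroll - 0.5)
    bias_s <- calibrate_gyro_bias(shank, window = preroll - 0.5)
    incl_t <- run_observer(thigh, observer, bias_t)
    incl_s <- run_observer(shank, observer, bias_s)
    est <- knee_angle(incl_t, incl_s)
    est <- window_series(est, from = clock_skew + preroll + ramp + settle)
    ref <- window_series(reference_angle(full, reference_rate, segment = "knee"),
                         from = preroll + ramp + settle)
    per_speed[[paste0(sp, "km/h")]] <- verify_agreement(est, ref, max_lag)
  }
  tab <- do.call(rbind, lapply(names(per_speed), function(nm) {
    s <- per_speed[[nm]]
    data.frame(speed = nm, rmse = s$rmse, std_dev = s$std_dev,
               mean_diff = s$mean_diff, mean_abs_diff = s$mean_abs_diff,
               min_diff = s$min_diff, max_diff = s$max_diff, n = s$n)
  }))
  config_echo <- list(experiment = "gait", speeds = speeds,
                      duration = duration, wearable_rate = wearable_rate,
                      reference_rate = reference_rate,
                      thigh_mount = thigh_mount, shank_mount = shank_mount,
                      accel_noise_sd = accel_noise_sd,
                      gyro_noise_sd = gyro_noise_sd,
                      gyro_bias_range = gyro_bias_range, seed = seed,
                      preroll = preroll, ramp = ramp,
                      clock_skew = clock_skew, settle = settle,
                      max_lag = max_lag, observer = unclass(observer))
  files <- NULL
  if (!is.null(out_dir))
    files <- .write_experiment_artifacts(out_dir, "gait", config_echo,
                                         per_speed, NULL, NULL, table = tab)
  list(per_speed = per_speed, table = tab, config = config_echo,
       files = files)
}

.stats_as_list <- function(s) {
  out <- unclass(s)
  attr(out, "offset") <- NULL
  out$offset_s <- attr(s, "offset")
  out
}

.write_experiment_artifacts <- function(out_dir, name, config_echo, stats_list,
                                        streams = NULL, series = NULL,
                                        table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)  # no partial artifacts
  manifest <- list(experiment = name, package_version = "0.1.0",
                   config = config_echo)
  p <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  p <- file.path(out_dir, paste0(name, "_stats.json"))
  jsonlite::write_json(lapply(stats_list, .stats_as_list), p,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  for (nm in names(streams)) {
    p <- file.path(out_dir, paste0(name, "_", nm, ".csv"))
    write_imu_csv(streams[[nm]], p)
    files <- c(files, p, paste0(p, ".json"))
  }
  for (nm in names(series)) {
    p <- file.path(out_dir, paste0(name, "_", nm, ".csv"))
    write_angle_csv(series[[nm]], p)
    files <- c(files, p)
  }
  if (!is.null(table)) {
    p <- file.path(out_dir, paste0(name, "_table.csv"))
    write.csv(table, p, row.names = FALSE)
    files <- c(files, p)
  }
  ok <- TRUE
  files
}
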