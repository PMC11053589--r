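#' Timestamped scalar angle series
#'
#' The basic container for inclination, joint-angle and reference-angle
#' signals.  Angles are stored in radians; timestamps are absolute seconds.
#'
#' @param times Numeric vector of timestamps in seconds, strictly increasing.
#' @param angle Numeric vector of angles in radians, same length as `times`.
#' @param sensor_id Optional character label identifying the source sensor.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(times, angle, sensor_id = NULL) {
  times <- as.numeric(times)
  angle <- as.numeric(angle)
  if (length(times) != length(angle))
    stop("`times` and `angle` must have the same length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(angle)))
    stop("`times` and `angle` must be finite")
  structure(list(times = times, angle = angle, sensor_id = sensor_id),
            class = "angle_series")
}

#' @export
length.angle_series <- function(x) length(x$times)

#' @export
print.angle_series <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<angle_series> %d samples%s\n", n,
              if (is.null(x$sensor_id)) "" else paste0(" [", x$sensor_id, "]")))
  if (n > 0)
    cat(sprintf("  t: %.3f .. %.3f s, angle: %.2f .. %.2f deg\n",
                x$times[1], x$times[n],
                min(x$angle) * 180 / pi, max(x$angle) * 180 / pi))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(time_s = x$times, angle_rad = x$angle)
}

#' Shift the time axis of an angle series
#'
#' @param series An [angle_series()].
#' @param offset Seconds to add to every timestamp.
#' @return A shifted `angle_series`.
#' @export
shift_series <- function(series, offset) {
  stopifnot(inherits(series, "angle_series"), .is_scalar_num(offset))
  angle_series(series$times + offset, series$angle, series$sensor_id)
}

#' Restrict an angle series to a time window
#'
#' @param series An [angle_series()].
#' @param from,to Window bounds in seconds (inclusive).
#' @return The restricted `angle_series`.
#' @export
window_series <- function(series, from = -Inf, to = Inf) {
  stopifnot(inherits(series, "angle_series"))
  keep <- series$times >= from & series$times <= to
  angle_series(series$times[keep], series$angle[keep], series$sensor_id)
}

#' Read and write angle series CSV files
#'
#' The on-disk format is a two-column CSV with header `time_s,angle_rad`.
#'
#' @param series An [angle_series()].
#' @param path File path.
#' @return `write_angle_csv` returns `path` invisibly; `read_angle_csv`
#'   returns an `angle_series`.
#' @export
write_angle_csv <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_csv
#' @export
read_angle_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "angle_rad") %in% names(df)))
    stop("expected columns time_s, angle_rad in ", path)
  angle_series(df$time_s, df$angle_rad)
}

#' Six-axis IMU sample stream
#'
#' One sensor's timestamped accelerometer (specific force, m/s^2) and
#' gyroscope (rad/s) samples, with the nominal sampling rate and the
#' configured full scales.
#'
#' @param sensor_id Character label.
#' @param times Strictly increasing timestamps (s).
#' @param specific_force n x 3 matrix, m/s^2 (sensor frame).
#' @param angular_rate n x 3 matrix, rad/s (sensor frame).
#' @param nominal_rate Nominal sampling rate in Hz.
#' @param accel_full_scale,gyro_full_scale Saturation limits used when the
#'   stream was produced (m/s^2 and rad/s).
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(sensor_id, times, specific_force, angular_rate,
                       nominal_rate, accel_full_scale = 16 * 9.81,
                       gyro_full_scale = 2000 * pi / 180) {
  times <- as.numeric(times)
  specific_force <- as.matrix(specific_force)
  angular_rate <- as.matrix(angular_rate)
  n <- length(times)
  if (nrow(specific_force) != n || nrow(angular_rate) != n ||
      ncol(specific_force) != 3L || ncol(angular_rate) != 3L)
    stop("`specific_force` and `angular_rate` must be n x 3 matrices")
  if (n > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(abs(specific_force) > accel_full_scale + 1e-9, na.rm = TRUE))
    stop("specific force exceeds the accelerometer full scale")
  if (any(abs(angular_rate) > gyro_full_scale + 1e-9, na.rm = TRUE))
    stop("angular rate exceeds the gyroscope full scale")
  structure(list(sensor_id = sensor_id, times = times,
                 specific_force = specific_force, angular_rate = angular_rate,
                 nominal_rate = nominal_rate,
                 accel_full_scale = accel_full_scale,
                 gyro_full_scale = gyro_full_scale),
            class = "imu_stream")
}

#' @export
length.imu_stream <- function(x) length(x$times)

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> '%s': %d samples @ %g Hz nominal\n",
              x$sensor_id, length(x$times), x$nominal_rate))
  invisible(x)
}

#' Read and write IMU stream CSV files
#'
#' Columns are `time_s,ax,ay,az,gx,gy,gz` (m/s^2 and rad/s).  A JSON sidecar
#' `<path>.json` carries the sensor id, nominal rate and full scales.
#'
#' @param stream An [imu_stream()].
#' @param path CSV file path.
#' @return `write_imu_csv` returns `path` invisibly; `read_imu_csv` returns
#'   an `imu_stream`.
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(inherits(stream, "imu_stream"))
  df <- data.frame(time_s = stream$times,
                   ax = stream$specific_force[, 1],
                   ay = stream$specific_force[, 2],
                   az = stream$specific_force[, 3],
                   gx = stream$angular_rate[, 1],
                   gy = stream$angular_rate[, 2],
                   gz = stream$angular_rate[, 3])
  write.csv(df, path, row.names = FALSE)
  meta <- list(sensor_id = stream$sensor_id, nominal_rate = stream$nominal_rate,
               accel_full_scale = stream$accel_full_scale,
               gyro_full_scale = stream$gyro_full_scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ","), " in ", path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  imu_stream(sensor_id = meta$sensor_id %||% basename(path),
             times = df$time_s,
             specific_force = as.matrix(df[, c("ax", "ay", "az")]),
             angular_rate = as.matrix(df[, c("gx", "gy", "gz")]),
             nominal_rate = meta$nominal_rate %||% (1 / median(diff(df$time_s))),
             accel_full_scale = meta$accel_full_scale %||% (16 * 9.81),
             gyro_full_scale = meta$gyro_full_scale %||% (2000 * pi / 180))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
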