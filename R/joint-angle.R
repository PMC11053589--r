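#' Knee joint angle from two segment inclinations
#'
#' With one sensor on the thigh and one on the shank, both parallel to the
#' sagittal plane, the knee flexion angle is the difference of the two
#' inclinations: `knee = thigh - shank`, flexion positive, 0 at full
#' extension.  The shank series is linearly interpolated onto the thigh
#' timestamps (the thigh clock is the master) restricted to the temporal
#' overlap; the result is wrapped to (-pi, pi].
#'
#' @param thigh,shank [angle_series()] inclinations of the two segments.
#' @return An [angle_series()] of knee angles on the overlapping thigh
#'   timestamps.
#' @export
knee_angle <- function(thigh, shank) {
  stopifnot(inherits(thigh, "angle_series"), inherits(shank, "angle_series"))
  if (length(thigh) < 2L || length(shank) < 2L)
    stop("both series need at least two samples to interpolate")
  t0 <- max(thigh$times[1], shank$times[1])
  t1 <- min(thigh$times[length(thigh)], shank$times[length(shank)])
  if (t0 > t1) stop("thigh and shank series have no temporal overlap")
  keep <- thigh$times >= t0 & thigh$times <= t1
  tt <- thigh$times[keep]
  sh <- approx(shank$times, shank$angle, tt)$y
  angle_series(tt, .wrap_angle(thigh$angle[keep] - sh), sensor_id = "knee")
}

#' Static extension-offset calibration
#'
#' Mean knee angle over a quiet-standing window, to be subtracted so that
#' standing reads 0 deg.  The window must actually be still: its standard
#' deviation has to stay below `still_sd_max`.
#'
#' @param series A knee [angle_series()].
#' @param window Scalar duration (seconds from the series start) or
#'   `c(t0, t1)` absolute bounds.
#' @param still_sd_max Stillness threshold on the angle sd, radians
#'   (default 0.5 deg).
#' @return Offset in radians.
#' @export
extension_offset_calibration <- function(series, window = NULL,
                                         still_sd_max = .deg2rad(0.5)) {
  stopifnot(inherits(series, "angle_series"), length(series) > 0L)
  t <- series$times
  keep <- if (is.null(window)) rep(TRUE, length(t))
          else if (length(window) == 1L) t <= t[1] + window
          else t >= window[1] & t <= window[2]
  if (!any(keep)) stop("calibration window contains no samples")
  a <- series$angle[keep]
  if (length(a) > 1L && sd(a) > still_sd_max)
    stop_not_stationary(
      sprintf("knee angle sd %.3f deg exceeds %.3f deg: subject not still",
              .rad2deg(sd(a)), .rad2deg(still_sd_max)), check = "angle_sd")
  mean(a)
}
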