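## Builders for small in-code fixtures.

G <- 9.81
DEG <- pi / 180

## Stationary stream: sensor tilted by `tilt` rad, optional noise/bias.
make_stationary_stream <- function(n = 200, rate = 50, tilt = 0,
                                   accel_noise = 0, gyro_noise = 0,
                                   bias = c(0, 0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  acc <- matrix(rep(c(G * sin(tilt), 0, G * cos(tilt)), each = n), n, 3) +
    matrix(rnorm(3 * n, sd = accel_noise), n, 3)
  gyr <- matrix(rep(bias, each = n), n, 3) +
    matrix(rnorm(3 * n, sd = gyro_noise), n, 3)
  imu_stream("stationary", t, acc, gyr, rate)
}

## Trajectory rotating at constant rate about the sagittal axis.
make_constant_rate_trajectory <- function(omega, duration = 2, dt = 1e-3) {
  t <- seq(0, duration, by = dt)
  n <- length(t)
  motion_trajectory(t, list(
    arm = list(angle = omega * t, rate = rep(omega, n),
               accel = rep(0, n), pivot_accel = matrix(0, n, 3))))
}

zero_noise <- function() imu_noise_model(0, 0, gyro_bias = c(0, 0, 0))

## Brute-force reference for the metrics-store filter semantics.
brute_filter <- function(df, filters) {
  keep <- rep(TRUE, nrow(df))
  for (f in filters) {
    v <- df[[f$column]]
    keep <- keep & switch(f$op, eq = v == f$value, gt = v > f$value,
                          lt = v < f$value)
  }
  df[keep, , drop = FALSE]
}
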