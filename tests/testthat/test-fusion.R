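test_that("bias calibration returns the exact mean of constant gyro samples", {
  s <- make_stationary_stream(n = 100, bias = c(0.01, -0.02, 0.005))
  b <- calibrate_gyro_bias(s)
  expect_equal(unname(b$bias), c(0.01, -0.02, 0.005))
  expect_equal(b$n_samples, 100L)
})

test_that("bias recovery from noisy samples is within 3 sigma / sqrt(N)", {
  truth <- c(0.012, -0.007, 0.019)
  s <- make_stationary_stream(n = 500, gyro_noise = 0.005, bias = truth,
                              seed = 11)
  b <- calibrate_gyro_bias(s)
  expect_true(all(abs(b$bias - truth) <= 3 * 0.005 / sqrt(500)))
})

test_that("non-stationary streams are rejected with a named check", {
  swing <- imu_from_trajectory(
    simulate_pendulum(pendulum_config(initial_angle = 30 * DEG, duration = 3)),
    "pendulum", 0.25, 50, zero_noise())
  expect_error(calibrate_gyro_bias(swing),
               class = "gaitfusion_not_stationary")
  err <- tryCatch(calibrate_gyro_bias(swing), condition = identity)
  expect_equal(err$check, "gyro_sd")
  # free-falling-ish stream: quiet gyro but wrong accel norm
  n <- 100
  s <- imu_stream("x", (0:(n - 1)) / 50, matrix(1, n, 3), matrix(0, n, 3), 50)
  err <- tryCatch(calibrate_gyro_bias(s), condition = identity)
  expect_s3_class(err, "gaitfusion_not_stationary")
  expect_equal(err$check, "accel_norm")
  expect_error(calibrate_gyro_bias(make_stationary_stream(n = 10)),
               "need >=")
})

test_that("observer initialization follows the static specific-force rule", {
  expect_equal(observer_init(c(0, 0, G))$gravity_dir, c(0, 0, -1))
  expect_equal(observer_init(c(G, 0, 0))$gravity_dir, c(-1, 0, 0))
  expect_error(observer_init(c(0, 0, 0)))
})

test_that("gyro-only propagation matches the closed-form rotation", {
  w <- 0.7; dt <- 0.02; nstep <- 100
  params <- observer_params()
  st <- observer_init(c(0, 0, 2 * G), params, time = 0)  # norm 2g gates out
  g0 <- st$gravity_dir
  for (i in seq_len(nstep))
    st <- observer_step(st, i * dt, c(0, 0, 2 * G), c(0, w, 0),
                        zero_gyro_bias(), params)
  ang <- -w * nstep * dt
  expected <- c(cos(ang) * g0[1] + sin(ang) * g0[3], g0[2],
                -sin(ang) * g0[1] + cos(ang) * g0[3])
  expect_lt(max(abs(st$gravity_dir - expected)), 1e-6)
})

test_that("out-of-gate accelerometer samples leave the predict-only state", {
  params <- observer_params()
  st <- observer_init(c(0, 0, G), params)
  gated <- observer_step(st, 0.02, c(0, 0, 2 * G), c(0, 0.3, 0),
                         zero_gyro_bias(), params)
  # predict-only by hand: rotate gravity by -omega * dt about y
  ang <- -0.3 * 0.02
  g <- st$gravity_dir
  pred <- c(cos(ang) * g[1] + sin(ang) * g[3], g[2],
            -sin(ang) * g[1] + cos(ang) * g[3])
  expect_equal(gated$gravity_dir, pred / sqrt(sum(pred^2)), tolerance = 1e-12)
  expect_error(observer_step(gated, 0.02, c(0, 0, G), c(0, 0, 0)),
               "strictly increasing")
})

test_that("inclination extraction follows the sign convention", {
  mk <- function(gd) structure(list(gravity_dir = gd), class = "gravity_observer_state")
  expect_equal(inclination_from_state(mk(c(0, 0, -1))), 0)
  expect_equal(inclination_from_state(mk(c(-sin(30 * DEG), 0, -cos(30 * DEG)))),
               30 * DEG)
  expect_equal(inclination_from_state(mk(c(-1, 0, 0))), pi / 2)
})

test_that("observer on a stationary tilted stream is accurate and drift-free", {
  s <- make_stationary_stream(n = 600, tilt = 20 * DEG)
  incl <- run_observer(s, bias = zero_gyro_bias())
  expect_equal(length(incl), 600L)
  err <- abs(incl$angle - 20 * DEG) / DEG
  expect_lt(max(err), 0.1)
  # drift < 0.01 deg/min on the noiseless fixed point
  drift <- abs(incl$angle[600] - incl$angle[300]) / DEG / (6 / 60)
  expect_lt(drift, 0.01)
})

test_that("unit norm and covariance PSD hold after arbitrary steps", {
  set.seed(3)
  params <- observer_params()
  st <- observer_init(c(0.5, 0.1, G), params)
  for (i in 1:200) {
    acc <- c(rnorm(2, sd = 2), G + rnorm(1, sd = 2))  # mix of gated/accepted
    st <- observer_step(st, i * 0.02, acc, rnorm(3, sd = 1),
                        zero_gyro_bias(), params)
    expect_lt(abs(sqrt(sum(st$gravity_dir^2)) - 1), 1e-9)
    P <- st$covariance
    expect_lt(max(abs(P - t(P))), 1e-12)
    expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
  }
})

test_that("self-calibration removes bias-induced inclination error", {
  bias <- c(0.008, 0.02, -0.012)
  s <- make_stationary_stream(n = 5000, gyro_noise = 0.005,
                              accel_noise = 0.05, bias = bias, seed = 5)
  raw <- run_observer(s, bias = zero_gyro_bias())
  cal <- run_observer(s, bias = calibrate_gyro_bias(s, window = 40))
  err_raw <- abs(raw$angle[5000]) / DEG
  err_cal <- abs(cal$angle[5000]) / DEG
  expect_gt(err_raw, err_cal)
  expect_lt(err_cal, 0.5)
})

test_that("non-finite samples are skipped with a warning, length preserved", {
  s <- make_stationary_stream(n = 100, tilt = 10 * DEG)
  s$specific_force[50, 2] <- NaN
  expect_warning(incl <- run_observer(s, bias = zero_gyro_bias()),
                 "skipped 1 non-finite")
  expect_equal(length(incl), 100L)
  expect_equal(incl$angle[50], incl$angle[49])
  empty <- imu_stream("e", numeric(0), matrix(0, 0, 3), matrix(0, 0, 3), 50)
  expect_equal(length(run_observer(empty, bias = zero_gyro_bias())), 0L)
})

test_that("inclination survives 32-bit float publication within 1e-6 rad", {
  x <- seq(-pi + 1e-6, pi, length.out = 1001)
  expect_lt(max(abs(as_float32(x) - x)), 1e-6)
})
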