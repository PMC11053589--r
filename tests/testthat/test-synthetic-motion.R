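test_that("pendulum at equilibrium stays at rest", {
  traj <- simulate_pendulum(pendulum_config(initial_angle = 0,
                                            initial_rate = 0, duration = 2))
  expect_equal(max(abs(traj$segments$pendulum$angle)), 0)
  expect_equal(max(abs(traj$segments$pendulum$rate)), 0)
})

test_that("small-angle period matches the closed-form pendulum", {
  cfg <- pendulum_config(length = 0.2485, damping = 0,
                         initial_angle = 2 * DEG, duration = 10)
  traj <- simulate_pendulum(cfg)
  th <- traj$segments$pendulum$angle
  t <- traj$times
  # zero crossings by linear interpolation; period = 2 * mean half-period
  s <- which(th[-1] * th[-length(th)] < 0)
  tc <- t[s] - th[s] * (t[s + 1] - t[s]) / (th[s + 1] - th[s])
  period <- 2 * mean(diff(tc))
  expect_lt(abs(period - 2 * pi * sqrt(0.2485 / G)) /
              (2 * pi * sqrt(0.2485 / G)), 0.005)
})

test_that("damped pendulum peak amplitudes decrease monotonically", {
  traj <- simulate_pendulum(pendulum_config(damping = 0.2,
                                            initial_angle = 30 * DEG,
                                            duration = 10))
  th <- traj$segments$pendulum$angle
  i <- which(diff(sign(diff(th))) == -2) + 1L  # local maxima
  peaks <- th[i][th[i] > 0]
  expect_gt(length(peaks), 3)
  expect_true(all(diff(peaks) < 0))
})

test_that("undamped pendulum conserves energy to < 0.1% over 60 s", {
  cfg <- pendulum_config(damping = 0, initial_angle = 30 * DEG, duration = 60)
  traj <- simulate_pendulum(cfg)
  e <- pendulum_energy(traj, cfg)
  expect_lt((max(e) - min(e)) / e[1], 1e-3)
})

test_that("gait swing flexion peaks land in the reported ranges", {
  kmax3 <- max(simulate_gait(gait_config(3, duration = 10))$
                 segments$knee$angle) / DEG
  expect_gte(kmax3, 60); expect_lte(kmax3, 70)
  kmax12 <- max(simulate_gait(gait_config(12, duration = 10))$
                  segments$knee$angle) / DEG
  expect_gte(kmax12, 80); expect_lte(kmax12, 90)
})

test_that("gait profiles are periodic and respect the hyperextension floor", {
  # cadence 1 Hz puts the stride period exactly on the 1 ms solver grid
  traj <- simulate_gait(gait_config(3, duration = 4, cadence = 1))
  k <- traj$segments$knee$angle
  shift <- 1000L  # one stride period in grid steps
  expect_lt(max(abs(k[(shift + 1):length(k)] - k[1:(length(k) - shift)])), 1e-6)
  expect_gt(min(k), -5 * DEG)
})

test_that("trajectory rates are consistent with finite-differenced angles", {
  traj <- simulate_gait(gait_config(6, duration = 5))
  for (seg in c("thigh", "shank")) {
    s <- traj$segments[[seg]]
    fd <- diff(s$angle) / diff(traj$times)
    mid <- (s$rate[-1] + s$rate[-length(s$rate)]) / 2
    expect_lt(max(abs(fd - mid)), 1e-3)
  }
})

test_that("static IMU reads specific force (0,0,+g) and silent gyro", {
  traj <- simulate_pendulum(pendulum_config(initial_angle = 0, duration = 2))
  s <- imu_from_trajectory(traj, "pendulum", mount_radius = 0.2, rate = 50,
                           noise = zero_noise())
  expect_equal(max(abs(s$angular_rate)), 0)
  expect_equal(unname(s$specific_force[1, ]), c(0, 0, G))
  expect_lt(max(abs(sqrt(rowSums(s$specific_force^2)) - G)), 1e-9)
})

test_that("constant rotation at zero mount radius: gyro reads -rate, norm g", {
  w <- 0.7
  traj <- make_constant_rate_trajectory(w)
  s <- imu_from_trajectory(traj, "arm", mount_radius = 0, rate = 50,
                           noise = zero_noise())
  expect_equal(unname(s$angular_rate[, 2]), rep(-w, length(s$times)))
  expect_lt(max(abs(sqrt(rowSums(s$specific_force^2)) - G)), 1e-9)
})

test_that("gyro saturates at the configured full scale", {
  w <- 2500 * DEG  # beyond the 2000 dps full scale
  traj <- make_constant_rate_trajectory(w, duration = 0.5)
  s <- imu_from_trajectory(traj, "arm", mount_radius = 0, rate = 50,
                           noise = zero_noise())
  expect_equal(unname(s$angular_rate[, 2]), rep(-2000 * DEG, length(s$times)))
  expect_lte(max(abs(s$angular_rate)), 2000 * DEG)
})

test_that("turning-point tangential acceleration equals r * theta''", {
  cfg <- pendulum_config(length = 0.3, damping = 0, initial_angle = 30 * DEG,
                         duration = 1)
  traj <- simulate_pendulum(cfg)
  r <- 0.3
  s <- imu_from_trajectory(traj, "pendulum", mount_radius = r, rate = 100,
                           noise = zero_noise())
  # t = 0 is a turning point: theta = theta_max, theta' = 0
  th_dd <- -(G / cfg$length) * sin(cfg$initial_angle)
  expect_equal(unname(s$specific_force[1, 1]) - G * sin(cfg$initial_angle),
               r * th_dd, tolerance = 1e-12)
  expect_equal(unname(s$specific_force[1, 3]), G * cos(cfg$initial_angle),
               tolerance = 1e-12)
})

test_that("reference angle resampling is deterministic and endpoint-exact", {
  traj <- simulate_gait(gait_config(3, duration = 5))
  r1 <- reference_angle(traj, rate = 200)
  r2 <- reference_angle(traj, rate = 400)
  shared <- match(r1$times, r2$times)
  expect_false(anyNA(shared))
  expect_identical(r1$angle, r2$angle[shared])
  # rate above grid density: endpoints preserved exactly
  r3 <- reference_angle(traj, rate = 5000)
  expect_identical(r3$angle[1], traj$segments$knee$angle[1])
  # pendulum at equilibrium -> all-zero series
  p <- simulate_pendulum(pendulum_config(initial_angle = 0, duration = 2))
  expect_equal(max(abs(reference_angle(p, 220)$angle)), 0)
})

test_that("fixed seed gives bit-identical streams; unknown segment errors", {
  traj <- simulate_gait(gait_config(6, duration = 5))
  n <- imu_noise_model(seed = 42)
  s1 <- imu_from_trajectory(traj, "thigh", 0.25, 50, n)
  s2 <- imu_from_trajectory(traj, "thigh", 0.25, 50, n)
  expect_identical(s1, s2)
  expect_error(imu_from_trajectory(traj, "femur", 0.25, 50, n),
               "unknown segment")
})

test_that("config invariants are enforced", {
  expect_error(pendulum_config(length = 0))
  expect_error(pendulum_config(duration = -1))
  expect_error(pendulum_config(solver_dt = 2, duration = 1))
  expect_error(gait_config(0))
  expect_error(gait_config(3, duration = 0.5), "stride")
})

test_that("IMU stream CSV round-trips with its sidecar", {
  traj <- simulate_gait(gait_config(3, duration = 3))
  s <- imu_from_trajectory(traj, "thigh", 0.25, 50,
                           imu_noise_model(seed = 7), sensor_id = "thigh")
  p <- file.path(tempdir(), "thigh.csv")
  write_imu_csv(s, p)
  s2 <- read_imu_csv(p)
  expect_equal(s2$times, s$times)
  expect_equal(unname(s2$specific_force), unname(s$specific_force))
  expect_equal(s2$sensor_id, "thigh")
  expect_equal(s2$nominal_rate, 50)
})
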