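test_that("gravity torque is zero at neutral and has the right sign and value", {
  cfg_dn <- plant_config(hand_mass = 0.5, cog_offset = 0.06,
                         orientation = "downward")
  cfg_up <- plant_config(hand_mass = 0.5, cog_offset = 0.06,
                         orientation = "upward")
  expect_equal(gravity_torque(wrist_state(0, 0), cfg_dn),
               c(fe = 0, rud = 0))
  expect_equal(gravity_torque(wrist_state(0, 0), cfg_up),
               c(fe = 0, rud = 0))
  # upward: destabilizing, same sign as the deflection
  t_up <- gravity_torque(wrist_state(10, -5), cfg_up)
  expect_gt(t_up[["fe"]], 0)
  expect_lt(t_up[["rud"]], 0)
  # downward: restoring pendulum torque -m g d sin(theta)
  t_dn <- gravity_torque(wrist_state(10, 0), cfg_dn)
  expect_equal(t_dn[["fe"]], -0.5 * 9.81 * 0.06 * sin(10 * pi / 180),
               tolerance = 1e-12)
})

test_that("muscle torques equal the brute-force moment-arm summation", {
  mus <- wrist_muscles()
  expect_equal(muscle_torques(rep(0, 6), mus), c(fe = 0, rud = 0))
  one <- data.frame(name = "X", pcsa_cm2 = 1, r_fe_mm = 15, r_rud_mm = 0,
                    f_max_N = 25)
  expect_equal(muscle_torques(10, one), c(fe = 0.15, rud = 0))
  set.seed(11)
  for (rep in 1:20) {
    f <- runif(6, 0, 80)
    tq <- muscle_torques(f, mus)
    # independent per-element summation
    t_fe <- 0; t_rud <- 0
    for (i in 1:6) {
      t_fe <- t_fe + mus$r_fe_mm[i] / 1000 * f[i]
      t_rud <- t_rud + mus$r_rud_mm[i] / 1000 * f[i]
    }
    expect_equal(unname(tq), c(t_fe, t_rud), tolerance = 1e-12)
  }
  expect_error(muscle_torques(c(-1, rep(1, 5)), mus), "nonnegative")
})

test_that("tendon excursion is linear in angle with slope equal to the arm", {
  mus <- wrist_muscles()
  expect_equal(unname(tendon_excursion(wrist_state(0, 0), mus)),
               rep(0, 6))
  one <- data.frame(name = "X", pcsa_cm2 = 1, r_fe_mm = 15, r_rud_mm = 0,
                    f_max_N = 25)
  expect_equal(unname(tendon_excursion(wrist_state(30, 0), one)),
               15 * 30 * pi / 180, tolerance = 1e-9)
  # finite-difference slope over a sweep reproduces the arms
  h <- 0.01
  for (axis in 1:2) {
    for (a in c(-20, 0, 20)) {
      th <- c(0, 0); th[axis] <- a
      thp <- th; thp[axis] <- a + h
      de <- (tendon_excursion(wrist_state(thp[1], thp[2]), mus) -
               tendon_excursion(wrist_state(th[1], th[2]), mus)) /
        (h * pi / 180)
      expect_equal(unname(de), moment_arm_matrix(mus)[, axis],
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("step_dynamics holds equilibrium and matches a hand-computed step", {
  pl <- quiet_plant()
  st <- plant_state(pl)
  st2 <- step_dynamics(st, rep(0, 6), pl)
  expect_equal(st2$wrist$theta_fe, 0)
  expect_equal(st2$wrist$theta_rud, 0)
  expect_equal(unname(st2$cable_force), rep(0, 6))
  expect_false(st2$limit_hit)

  # single hand-computed symplectic-Euler substep
  cfgh <- plant_config(orientation = "downward", physics_dt = 0.005,
                       angle_noise_sd = 0, force_noise_sd = 0)
  plh <- wrist_plant(cfgh)
  th0 <- c(5, 0); om0 <- c(0, 0); h <- 0.005
  y <- stats::setNames(c(3, 0, 0, 0, 0, 0), MUSCLE_NAMES)  # FCR pulled 3 mm
  sth <- plant_state(plh, wrist_state(th0[1], th0[2]), actuator_pos = y)
  out <- step_dynamics(sth, y, plh, dt = h)
  R <- moment_arm_matrix(plh$muscles)
  e <- R %*% (th0 * pi / 180)
  f <- pmax(0, 20 * (y - e))              # k = 20 N/mm
  tau <- colSums(as.vector(f) * R) / 1000
  tau <- tau + c(-0.45 * 9.81 * 0.06 * sin(5 * pi / 180), 0)
  om1 <- (om0 * pi / 180) + h * (tau - 0.005 * om0 * pi / 180) / 0.002
  th1 <- th0 * pi / 180 + h * om1
  expect_equal(out$wrist$theta_fe, th1[[1]] * 180 / pi, tolerance = 1e-10)
  expect_equal(out$wrist$omega_fe, om1[[1]] * 180 / pi, tolerance = 1e-10)
  expect_equal(unname(out$cable_force), unname(as.vector(f)),
               tolerance = 1e-10)

  expect_error(step_dynamics(st, rep(0, 6), pl, dt = 0), "dt")
  expect_error(step_dynamics(st, c(Inf, rep(0, 5)), pl), "finite")
  bad <- st
  bad$wrist$theta_fe <- NaN
  expect_error(step_dynamics(bad, rep(0, 6), pl), "diverged")
})

test_that("passive swing oscillates at the pendulum frequency and loses energy", {
  pl <- quiet_plant()
  pp <- simulate_passive(pl, theta0_fe = 5, duration = 10, dt = 0.001)
  zc <- which(diff(sign(pp$theta_fe)) != 0)
  expect_gt(length(zc), 10)
  f_meas <- (length(zc) - 1) / 2 / (pp$time[zc[length(zc)]] - pp$time[zc[1]])
  cfg <- pl$config
  f_theo <- sqrt(cfg$hand_mass * cfg$gravity * cfg$cog_offset /
                   cfg$inertia_fe) / (2 * pi)
  expect_lt(abs(f_meas / f_theo - 1), 0.02)
  # energy decays monotonically up to integrator noise
  expect_lt(pp$energy[nrow(pp)], pp$energy[1])
  upticks <- diff(pp$energy)
  expect_lt(max(upticks), 1e-8)
})

test_that("halving the physics step reduces trajectory error by about first order", {
  ref <- simulate_passive(wrist_plant(plant_config(physics_dt = 2.5e-4)),
                          theta0_fe = 8, duration = 2, dt = 2.5e-4)
  run_at <- function(dt) {
    simulate_passive(wrist_plant(plant_config(physics_dt = dt)),
                     theta0_fe = 8, duration = 2, dt = dt)
  }
  err_at <- function(dt) {
    tr <- run_at(dt)
    ts <- seq(0.1, 2, by = 0.1)
    a <- stats::approx(tr$time, tr$theta_fe, ts)$y
    b <- stats::approx(ref$time, ref$theta_fe, ts)$y
    max(abs(a - b))
  }
  e4 <- err_at(4e-3)
  e2 <- err_at(2e-3)
  expect_gte(e4 / e2, 1.8)
})

test_that("sensing is exact at zero noise, reproducible, and calibrated", {
  pl <- quiet_plant()
  st <- plant_state(pl, wrist_state(7, -3))
  m <- sense(st, pl, rng_stream(1))
  expect_equal(unname(m$angles), c(7, -3))
  pln <- noisy_plant(angle_noise_sd = 0.2)
  st <- plant_state(pln, wrist_state(0, 0))
  a <- sense(st, pln, rng_stream(42))
  b <- sense(st, pln, rng_stream(42))
  expect_identical(a, b)
  rng <- rng_stream(7)
  draws <- replicate(5000, sense(st, pln, rng)$angles[["fe"]])
  expect_lt(abs(stats::sd(draws) / 0.2 - 1), 0.05)
})

test_that("moment-arm estimation recovers the plant truth", {
  pl <- quiet_plant()
  est <- estimate_moment_arms(pl)
  expect_equal(est, moment_arm_matrix(pl$muscles), tolerance = 1e-9)
  pln <- noisy_plant()  # 0.1 deg angle noise
  est_n <- estimate_moment_arms(pln, seed = 5)
  rel <- abs(est_n - moment_arm_matrix(pln$muscles)) /
    abs(moment_arm_matrix(pln$muscles))
  expect_lt(max(rel), 0.02)
  expect_error(estimate_moment_arms(pl, range_deg = c(0, 0)), "range")
  expect_error(estimate_moment_arms(pl, n_samples = 3), "samples")
})

test_that("cable forces stay nonnegative throughout a closed-loop run", {
  pl <- noisy_plant()
  res <- run_simulation(pl, default_controller("hybrid"), short_spec(),
                        seed = 3)
  fcols <- paste0("F_", MUSCLE_NAMES)
  expect_true(all(as.matrix(res$series[, fcols]) >= 0))
})
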