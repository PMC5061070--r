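test_that("position control commands the nominal excursions at zero error", {
  mus <- wrist_muscles()
  cc <- default_controller("position")
  st <- controller_state(cc, mus)
  desired <- list(theta_fe_d = 12, theta_rud_d = -4,
                  accel_fe_d = 0, accel_rud_d = 0)
  meas <- c(fe = 12, rud = -4)
  out <- position_control_step(desired, meas, mus, cc, st, 0.005)
  nominal <- tendon_excursion(wrist_state(12, -4), mus)
  expect_equal(out$output$actuator_cmd, nominal, tolerance = 1e-12)
  expect_true(all(out$output$mode == "position"))
})

test_that("corrective excursions are distributed by moment-arm ratios", {
  mus <- wrist_muscles()
  cc <- controller_config("position",
                          axis_gains = list(fe = pid_gains(kp = 0.5),
                                            rud = pid_gains(kp = 0)))
  st <- controller_state(cc, mus)
  desired <- list(theta_fe_d = 0, theta_rud_d = 0)
  out <- position_control_step(desired, c(fe = -2, rud = 0), mus, cc, st,
                               0.005)
  dy <- out$output$actuator_cmd  # nominal is zero at neutral
  R <- moment_arm_matrix(mus)
  # proportional to the FE arms, normalized to |ECRB|
  expect_equal(unname(dy / R[, "fe"]),
               rep(0.5 * 2 / abs(R["ECRB", "fe"]), 6), tolerance = 1e-12)
})

test_that("ECRB with a zero arm on a commanded axis is rejected at construction", {
  mus <- wrist_muscles()
  mus$r_rud_mm[mus$name == "ECRB"] <- 0
  cc <- default_controller("position")
  expect_error(controller_state(cc, mus), "ECRB")
})

test_that("force control holds its command at zero error and clamps negatives", {
  mus <- wrist_muscles()
  cc <- default_controller("position")  # gains irrelevant here
  ccf <- controller_config("force", axis_gains = cc$axis_gains,
                           force_gains = pid_gains(kp = 2, ki = 1))
  st <- controller_state(ccf, mus)
  fd <- stats::setNames(rep(15, 6), mus$name)
  out <- force_control_step(fd, fd, mus, ccf, st, 0.005)
  expect_equal(unname(out$output$actuator_cmd), rep(0, 6))
  expect_true(all(out$output$mode == "force_track"))
  expect_warning(
    force_control_step(stats::setNames(c(-5, rep(10, 5)), mus$name),
                       fd, mus, ccf, out$state, 0.005),
    "clamped")
})

test_that("a single muscle settles on a commanded force step through the cable", {
  # one taut cable on a locked joint: loop converges to the setpoint
  pl <- quiet_plant(joint_limits = list(fe = c(-1e-6, 1e-6),
                                        rud = c(-1e-6, 1e-6)))
  mus <- pl$muscles
  cc <- controller_config("force",
                          axis_gains = default_gains()[c("fe", "rud")],
                          force_gains = default_gains()$force)
  st <- controller_state(cc, mus)
  ps <- plant_state(pl)
  target <- stats::setNames(c(20, rep(0, 5)), mus$name)
  f_hist <- numeric(200)
  for (k in 1:200) {  # 1 s
    out <- force_control_step(target, ps$cable_force, mus, cc, st, 0.005)
    st <- out$state
    ps <- step_dynamics(ps, out$output$actuator_cmd, pl, 0.005)
    f_hist[k] <- ps$cable_force[["FCR"]]
  }
  expect_lt(abs(f_hist[200] - 20) / 20, 0.02)
})

test_that("hybrid equals position control while all forces sit inside the band", {
  mus <- wrist_muscles()
  cc <- default_controller("hybrid")
  stp <- controller_state(default_controller("position"), mus)
  sth <- controller_state(cc, mus)
  desired <- list(theta_fe_d = 5, theta_rud_d = 1)
  meas <- c(fe = 4.5, rud = 1.2)
  inside <- stats::setNames(rep(25, 6), mus$name)  # within (12, fmax-2)
  p <- position_control_step(desired, meas, mus,
                             default_controller("position"), stp, 0.005)
  h <- hybrid_control_step(desired, meas, inside, mus, cc, sth, 0.005)
  expect_equal(h$output$actuator_cmd, p$output$actuator_cmd,
               tolerance = 1e-12)
  expect_true(all(h$output$mode == "position"))
})

test_that("a muscle below the floor is handed to force control targeting F0", {
  mus <- wrist_muscles()
  cc <- default_controller("hybrid")
  st <- controller_state(cc, mus)
  desired <- list(theta_fe_d = 0, theta_rud_d = 0)
  forces <- stats::setNames(rep(25, 6), mus$name)
  forces[["ECU"]] <- 4  # below F0 = 10
  out <- hybrid_control_step(desired, c(fe = 0, rud = 0), forces, mus,
                             cc, st, 0.005)
  expect_equal(out$output$mode[["ECU"]], "force_low")
  expect_equal(out$output$desired_forces[["ECU"]], 10)
  expect_true(all(out$output$mode[names(forces) != "ECU"] == "position"))
})

test_that("hybrid reduces to position control when the bounds are disabled", {
  pl <- quiet_plant()
  spec <- short_spec(amp_fe = 8, n_cycles = 2)
  ccp <- default_controller("position")
  cch <- default_controller("hybrid")
  cch$f0 <- 0
  cch$f_max <- rep(Inf, 6)
  cch$hysteresis_band <- 0
  rp <- run_simulation(pl, ccp, spec, seed = 9)
  rh <- run_simulation(pl, cch, spec, seed = 9)
  expect_equal(rh$series$theta_fe, rp$series$theta_fe, tolerance = 1e-9)
  expect_equal(rh$series$theta_rud, rp$series$theta_rud, tolerance = 1e-9)
  expect_true(all(rh$series[, paste0("mode_", MUSCLE_NAMES)] == 0))
})

test_that("cascade at rest distributes the impedance budget by the QP", {
  mus <- wrist_muscles()
  pl_cfg <- plant_config(gravity = 0)
  cc <- default_controller("cascade", plant_cfg = pl_cfg)
  st <- controller_state(cc, mus)
  desired <- list(theta_fe_d = 0, theta_rud_d = 0,
                  accel_fe_d = 0, accel_rud_d = 0)
  out <- cascade_control_step(desired, c(fe = 0, rud = 0),
                              stats::setNames(rep(0, 6), mus$name),
                              mus, cc, st, 0.005)
  ref <- solve_force_distribution(torque_demand(0, 0), mus,
                                  qp_config(rho = 140))
  expect_equal(out$output$desired_forces, ref$forces, tolerance = 1e-9)
  expect_equal(sum(out$output$desired_forces), 140, tolerance = 1e-7)
  expect_true(all(out$output$mode == "force_track"))
  expect_true(out$output$qp_feasible)
})

test_that("Ziegler-Nichols recovers the analytic ultimate gain of a triple lag", {
  # plant 1/(s+1)^3 under proportional control: K_u = 8, T_u = 2*pi/sqrt(3)
  probe <- function(kp) {
    dt <- 0.002
    n <- 30000
    x <- c(0, 0, 0)
    y <- numeric(n)
    tm <- numeric(n)
    deriv <- function(x, u) c(u - x[1], x[1] - x[2], x[2] - x[3])
    for (k in seq_len(n)) {
      u <- kp * (1 - x[3])
      k1 <- deriv(x, u)
      k2 <- deriv(x + dt / 2 * k1, u)
      k3 <- deriv(x + dt / 2 * k2, u)
      k4 <- deriv(x + dt * k3, u)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[k] <- x[3]
      tm[k] <- k * dt
    }
    list(time = tm, y = y, setpoint = 1)
  }
  zn <- ziegler_nichols_tune(probe, kp_init = 1, kp_max = 64)
  expect_lt(abs(zn$K_u / 8 - 1), 0.05)
  expect_lt(abs(zn$T_u / (2 * pi / sqrt(3)) - 1), 0.05)
  expect_equal(zn$gains$kp, 0.6 * zn$K_u)
  expect_equal(zn$gains$ki, 1.2 * zn$K_u / zn$T_u)
})

test_that("tuning fails loudly on a loop with no ultimate gain in range", {
  # first-order lag never sustains an oscillation under P control
  probe <- function(kp) {
    dt <- 0.01
    n <- 2000
    x <- 0
    y <- numeric(n)
    for (k in seq_len(n)) {
      x <- x + dt * (kp * (1 - x) - x)
      y[k] <- x
    }
    list(time = seq_len(n) * dt, y = y, setpoint = 1)
  }
  expect_error(ziegler_nichols_tune(probe, kp_init = 0.5, kp_max = 50),
               "overdamped|no sustained")
})

test_that("identical seeds give identical closed-loop records", {
  pl <- noisy_plant()
  cc <- default_controller("hybrid")
  spec <- short_spec(amp_fe = 10, n_cycles = 2)
  a <- run_simulation(pl, cc, spec, seed = 17)
  b <- run_simulation(pl, cc, spec, seed = 17)
  expect_identical(a$series, b$series)
})
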