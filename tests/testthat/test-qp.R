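test_that("symmetric two-muscle reduction splits rho equally", {
  m2 <- data.frame(name = c("A", "B"), pcsa_cm2 = c(2, 2),
                   r_fe_mm = c(15, -15), r_rud_mm = c(0, 0))
  s <- solve_force_distribution(torque_demand(0, 0), m2,
                                qp_config(rho = 8))
  expect_true(s$feasible)
  expect_equal(unname(s$forces), c(4, 4), tolerance = 1e-9)
  o <- oracle_enumerate(torque_demand(0, 0), m2, qp_config(rho = 8))
  expect_equal(unname(o$forces), c(4, 4), tolerance = 1e-9)
})

test_that("feasible solutions satisfy all three constraints exactly", {
  mus <- wrist_muscles()
  rng <- rng_stream(31)
  for (i in 1:50) {
    d <- torque_demand(rng$rnorm(1, sd = 0.3), rng$rnorm(1, sd = 0.15))
    s <- solve_force_distribution(d, mus, qp_config(rho = 140))
    expect_true(s$feasible)
    expect_true(all(s$forces >= -1e-9))
    expect_equal(sum(s$forces), 140, tolerance = 1e-7)
    tq <- muscle_torques(pmax(s$forces, 0), mus)
    expect_equal(unname(tq), c(d$t_fe, d$t_rud), tolerance = 1e-7)
  }
  # oracle agrees on a known instance and meets constraints to 1e-9
  o <- oracle_enumerate(torque_demand(0.5, 0.1), mus, qp_config(rho = 140))
  expect_true(o$feasible)
  expect_lt(max(abs(o$residuals)), 1e-9 * 140)
})

test_that("active-set solver matches the enumeration oracle on random instances", {
  rng <- rng_stream(97)
  n_agree <- 0L
  for (i in 1:400) {
    mus <- perturbed_muscles(rng)
    d <- torque_demand(rng$rnorm(1, sd = 0.5), rng$rnorm(1, sd = 0.25))
    rho <- 30 + abs(rng$rnorm(1, sd = 80))
    qp <- qp_config(rho = rho)
    a <- solve_force_distribution(d, mus, qp)
    b <- oracle_enumerate(d, mus, qp)
    expect_equal(a$feasible, b$feasible)
    if (b$feasible) {
      n_agree <- n_agree + 1L
      scale <- max(1, max(abs(b$forces)))
      expect_lt(max(abs(a$forces - b$forces)) / scale, 1e-6)
      expect_lt(abs(a$objective - b$objective) / max(1, b$objective),
                1e-6)
    }
  }
  expect_gt(n_agree, 200)  # the draw ranges produce mostly feasible cases
})

test_that("the minimizer is unique and invariant to muscle ordering and PCSA scale", {
  mus <- wrist_muscles()
  d <- torque_demand(0.4, -0.1)
  qp <- qp_config(rho = 140)
  base <- solve_force_distribution(d, mus, qp)
  # permuting the muscle rows permutes the solution, nothing else
  perm <- c(4, 2, 6, 1, 3, 5)
  sp <- solve_force_distribution(d, mus[perm, ], qp)
  expect_equal(unname(sp$forces[order(perm)]), unname(base$forces),
               tolerance = 1e-9)
  # uniform PCSA scaling leaves the minimizer unchanged
  mus2 <- mus
  mus2$pcsa_cm2 <- mus2$pcsa_cm2 * 3.7
  s2 <- solve_force_distribution(d, mus2, qp)
  expect_equal(unname(s2$forces), unname(base$forces), tolerance = 1e-8)
})

test_that("raising rho weakly raises the minimum and mean muscle force", {
  mus <- wrist_muscles()
  rng <- rng_stream(55)
  for (i in 1:25) {
    d <- torque_demand(rng$rnorm(1, sd = 0.3), rng$rnorm(1, sd = 0.1))
    lo <- solve_force_distribution(d, mus, qp_config(rho = 120))
    hi <- solve_force_distribution(d, mus, qp_config(rho = 160))
    if (!(lo$feasible && hi$feasible)) next
    expect_gte(min(hi$forces), min(lo$forces) - 1e-9)
    expect_gte(mean(hi$forces), mean(lo$forces) - 1e-9)
  }
})

test_that("an incompatible rho is flagged and the torque still honored", {
  mus <- wrist_muscles()
  d <- torque_demand(2, 0)       # needs ~130 N of total force
  s <- solve_force_distribution(d, mus, qp_config(rho = 20))
  expect_false(s$feasible)
  expect_true(s$rho_dropped)
  tq <- muscle_torques(pmax(s$forces, 0), mus)
  expect_equal(unname(tq), c(2, 0), tolerance = 1e-7)
  o <- oracle_enumerate(d, mus, qp_config(rho = 20))
  expect_false(o$feasible)
})

test_that("feasibility check computes the minimum total force", {
  mus <- wrist_muscles()
  z <- feasibility_check(torque_demand(0, 0), mus, 50)
  expect_equal(z$min_total_force, 0)
  expect_true(z$rho_feasible)
  # two-muscle closed form: the demand is exactly along muscle A's
  # moment-arm direction, and its antagonist can only add total force,
  # so the cheapest solution is A alone at |T| / r = 20 N
  m2 <- data.frame(name = c("A", "B"), pcsa_cm2 = c(2, 2),
                   r_fe_mm = c(15, -10), r_rud_mm = c(10, -8))
  fc <- feasibility_check(torque_demand(0.3, 0.2), m2, 100)
  expect_equal(fc$min_total_force, 20, tolerance = 1e-6)
  lo <- feasibility_check(torque_demand(2, 0), mus, 20)
  expect_false(lo$rho_feasible)
  expect_match(lo$reason, "below the minimum")
  # f_max caps the achievable total
  capped <- feasibility_check(torque_demand(0.5, 0.1), mus, 1000,
                              f_max = mus$f_max_N)
  expect_false(capped$rho_feasible)
  expect_lt(capped$max_total_force, 1000)
})
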