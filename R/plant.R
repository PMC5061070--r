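# Virtual 2-DOF tendon-driven wrist plant.
#
# Model: per-axis rigid-body dynamics with decoupled inertias,
#   I_j * theta_dd_j = T_muscle_j + T_gravity_j - b_j * theta_d_j
# cables as one-sided series springs F_i = max(0, k (y_i - e_i(theta)))
# with e_i the required tendon excursion, and rate-limited position
# servos as actuators.  Angles are degrees at every interface and
# radians internally.

DEG2RAD <- pi / 180

#' Plant configuration
#'
#' Physical and sensing parameters of the virtual wrist rig.  Defaults
#' describe a 50th-percentile male hand (mass 0.45 kg, centre of gravity
#' 0.06 m distal of the wrist, inertia 2e-3 kg m^2 per axis) hanging
#' from stiff steel cables (2e4 N/m) driven by linear actuators, sensed
#' by motion capture (0.1 deg noise SD) and in-line load cells
#' (0.1 N noise SD) at a 5 ms control period.
#'
#' @param hand_mass Hand mass, kg.
#' @param cog_offset Distance from wrist centre to hand centre of
#'   gravity, m.
#' @param inertia_fe,inertia_rud Hand inertia about each axis, kg m^2.
#' @param damping_fe,damping_rud Viscous joint damping, N m s/rad.
#' @param orientation `"downward"` (hand below the elbow; gravity
#'   restores toward neutral) or `"upward"` (hand above the elbow;
#'   gravity destabilizes, an inverted pendulum).
#' @param gravity Gravitational acceleration, m/s^2.
#' @param cable_stiffness Series stiffness of each cable, N/m.
#' @param actuator_max_speed Actuator rate limit, m/s.
#' @param loop_period Control loop period, s.
#' @param physics_dt Internal integration substep, s.
#' @param angle_noise_sd Angle measurement noise SD, deg.
#' @param force_noise_sd Force measurement noise SD, N.
#' @param joint_limits List with elements `fe` and `rud`, each
#'   `c(lo, hi)` in deg; motion is hard-stopped at the limits.
#' @return A validated list of class `plant_config`.
#' @export
plant_config <- function(hand_mass = 0.45,
                         cog_offset = 0.06,
                         inertia_fe = 2e-3,
                         inertia_rud = 2e-3,
                         damping_fe = 5e-3,
                         damping_rud = 5e-3,
                         orientation = c("downward", "upward"),
                         gravity = 9.81,
                         cable_stiffness = 2e4,
                         actuator_max_speed = 0.1,
                         loop_period = 0.005,
                         physics_dt = 0.001,
                         angle_noise_sd = 0.1,
                         force_noise_sd = 0.1,
                         joint_limits = list(fe = c(-80, 80),
                                             rud = c(-40, 40))) {
  orientation <- match.arg(orientation)
  cfg <- list(hand_mass = hand_mass, cog_offset = cog_offset,
              inertia_fe = inertia_fe, inertia_rud = inertia_rud,
              damping_fe = damping_fe, damping_rud = damping_rud,
              orientation = orientation, gravity = gravity,
              cable_stiffness = cable_stiffness,
              actuator_max_speed = actuator_max_speed,
              loop_period = loop_period, physics_dt = physics_dt,
              angle_noise_sd = angle_noise_sd,
              force_noise_sd = force_noise_sd,
              joint_limits = joint_limits)
  validate_plant_config(cfg)
}

#' @rdname plant_config
#' @param cfg A candidate configuration list.
#' @export
validate_plant_config <- function(cfg) {
  pos <- c("hand_mass", "cog_offset", "inertia_fe", "inertia_rud",
           "cable_stiffness", "actuator_max_speed", "loop_period",
           "physics_dt")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("plant config field '", f, "' must be a positive number")
    }
  }
  nonneg <- c("damping_fe", "damping_rud", "gravity",
              "angle_noise_sd", "force_noise_sd")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop("plant config field '", f, "' must be a nonnegative number")
    }
  }
  if (!cfg$orientation %in% c("downward", "upward")) {
    stop("orientation must be 'downward' or 'upward'")
  }
  jl <- cfg$joint_limits
  if (!is.list(jl) || !all(c("fe", "rud") %in% names(jl)) ||
      any(vapply(jl[c("fe", "rud")], function(x) {
        length(x) != 2L || x[1] >= 0 || x[2] <= 0
      }, logical(1)))) {
    stop("joint_limits must bracket 0 for both fe and rud")
  }
  if (cfg$physics_dt > cfg$loop_period + 1e-12) {
    stop("physics_dt must not exceed loop_period")
  }
  class(cfg) <- "plant_config"
  cfg
}

#' Assemble a virtual wrist plant
#'
#' Bundles a [plant_config()] with a muscle table, precomputing the
#' moment-arm matrix used by the cable model.
#'
#' @param config A `plant_config`.
#' @param muscles A `muscle_table` (default [wrist_muscles()]).
#' @return A list of class `wrist_plant`.
#' @export
wrist_plant <- function(config = plant_config(), muscles = wrist_muscles()) {
  config <- validate_plant_config(unclass(config))
  muscles <- validate_muscle_table(muscles)
  structure(list(config = config, muscles = muscles,
                 R = moment_arm_matrix(muscles),
                 k_mm = config$cable_stiffness / 1000),
            class = "wrist_plant")
}

#' Wrist kinematic state
#'
#' @param theta_fe,theta_rud Joint angles, deg (flexion and ulnar
#'   deviation positive).
#' @param omega_fe,omega_rud Joint angular velocities, deg/s.
#' @param time Simulation time, s.
#' @return A list of class `wrist_state`.
#' @export
wrist_state <- function(theta_fe = 0, theta_rud = 0,
                        omega_fe = 0, omega_rud = 0, time = 0) {
  structure(list(theta_fe = theta_fe, theta_rud = theta_rud,
                 omega_fe = omega_fe, omega_rud = omega_rud,
                 time = time),
            class = "wrist_state")
}

#' Full plant state
#'
#' Combines the wrist state with per-muscle actuator positions (mm,
#' positive = reel in) and the resulting cable tensions (N, always
#' nonnegative: cables pull only).
#'
#' @param plant A `wrist_plant`.
#' @param wrist A `wrist_state`.
#' @param actuator_pos Named numeric vector of 6 actuator positions, mm.
#' @return A list of class `plant_state`.
#' @export
plant_state <- function(plant, wrist = wrist_state(),
                        actuator_pos = stats::setNames(numeric(6), MUSCLE_NAMES)) {
  f <- cable_forces(plant, wrist, actuator_pos)
  structure(list(wrist = wrist, actuator_pos = actuator_pos,
                 cable_force = f, limit_hit = FALSE),
            class = "plant_state")
}

# Tension in each cable given wrist pose and actuator positions (mm).
cable_forces <- function(plant, wrist, actuator_pos) {
  e <- excursion_mm(plant$R, wrist$theta_fe, wrist$theta_rud)
  stats::setNames(pmax(0, plant$k_mm * (actuator_pos - e)),
                  plant$muscles$name)
}

excursion_mm <- function(R, theta_fe_deg, theta_rud_deg) {
  drop(R %*% c(theta_fe_deg, theta_rud_deg)) * DEG2RAD
}

#' Gravitational torque on the hand
#'
#' In the downward orientation the hand hangs below the wrist and
#' gravity produces a restoring (pendulum) torque `-m g d sin(theta)`
#' about each axis; in the upward orientation the sign flips and the
#' plant is an inverted pendulum.
#'
#' @param wrist A `wrist_state`.
#' @param cfg A `plant_config`.
#' @return Named numeric `c(fe = , rud = )`, N m.
#' @export
gravity_torque <- function(wrist, cfg) {
  sgn <- if (cfg$orientation == "upward") 1 else -1
  mgd <- cfg$hand_mass * cfg$gravity * cfg$cog_offset
  c(fe = sgn * mgd * sin(wrist$theta_fe * DEG2RAD),
    rud = sgn * mgd * sin(wrist$theta_rud * DEG2RAD))
}

#' Joint torques produced by a set of cable forces
#'
#' `T_j = sum_i r_ij F_i`, with moment arms converted mm to m.
#'
#' @param forces Nonnegative numeric vector of 6 cable forces, N.
#' @param muscles A `muscle_table`.
#' @return Named numeric `c(fe = , rud = )`, N m.
#' @export
muscle_torques <- function(forces, muscles) {
  if (length(forces) != nrow(muscles)) stop("need one force per muscle")
  if (any(!is.finite(forces)) || any(forces < 0)) {
    stop("cable forces must be finite and nonnegative")
  }
  R <- moment_arm_matrix(muscles)
  tq <- drop(crossprod(R, forces)) / 1000
  c(fe = tq[["fe"]], rud = tq[["rud"]])
}

#' Required tendon excursion at a wrist pose
#'
#' With constant moment arms, the excursion of tendon i is
#' `e_i = r_i,fe theta_fe + r_i,rud theta_rud` (theta in radians),
#' positive when the tendon shortens toward its positive-torque
#' direction.  Its slope against joint angle is the moment arm, which is
#' what [estimate_moment_arms()] exploits.
#'
#' @param wrist A `wrist_state`.
#' @param muscles A `muscle_table`.
#' @return Named numeric vector of 6 excursions, mm.
#' @export
tendon_excursion <- function(wrist, muscles) {
  e <- excursion_mm(moment_arm_matrix(muscles), wrist$theta_fe, wrist$theta_rud)
  stats::setNames(e, muscles$name)
}

#' Advance the plant by one control period
#'
#' Symplectic-Euler integration of the per-axis rigid-body dynamics at
#' the internal physics substep, with the actuators slewing toward
#' their commanded positions at the rate limit, cable tensions
#' recomputed each substep (never negative), and joint limits enforced
#' as hard stops (velocity zeroed into the stop).
#'
#' @param state A `plant_state`.
#' @param actuator_cmd Numeric vector of 6 commanded actuator
#'   positions, mm.
#' @param plant A `wrist_plant`.
#' @param dt Time step, s (default: the configured loop period).
#' @return The updated `plant_state`; `$limit_hit` is `TRUE` if a joint
#'   limit was reached during the step.
#' @export
step_dynamics <- function(state, actuator_cmd, plant, dt = NULL) {
  cfg <- plant$config
  if (is.null(dt)) dt <- cfg$loop_period
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (any(!is.finite(actuator_cmd))) stop("actuator commands must be finite")
  w <- state$wrist
  if (any(!is.finite(c(w$theta_fe, w$theta_rud, w$omega_fe, w$omega_rud)))) {
    stop("plant state is non-finite; simulation diverged at t = ", w$time)
  }
  n_sub <- max(1L, as.integer(round(dt / cfg$physics_dt)))
  h <- dt / n_sub
  th <- c(w$theta_fe, w$theta_rud) * DEG2RAD
  om <- c(w$omega_fe, w$omega_rud) * DEG2RAD
  pos <- state$actuator_pos
  R <- plant$R
  k <- plant$k_mm
  inertia <- c(cfg$inertia_fe, cfg$inertia_rud)
  damping <- c(cfg$damping_fe, cfg$damping_rud)
  mgd <- cfg$hand_mass * cfg$gravity * cfg$cog_offset
  gsgn <- if (cfg$orientation == "upward") 1 else -1
  lim_lo <- c(cfg$joint_limits$fe[1], cfg$joint_limits$rud[1]) * DEG2RAD
  lim_hi <- c(cfg$joint_limits$fe[2], cfg$joint_limits$rud[2]) * DEG2RAD
  dmax <- cfg$actuator_max_speed * 1000 * h  # mm per substep
  limit_hit <- isTRUE(state$limit_hit)
  f <- state$cable_force
  for (s in seq_len(n_sub)) {
    dp <- actuator_cmd - pos
    pos <- pos + pmin(pmax(dp, -dmax), dmax)
    e <- drop(R %*% th)              # mm (th already rad)
    f <- pmax(0, k * (pos - e))
    t_m <- unname(drop(crossprod(R, f))) / 1000  # N m
    t_g <- gsgn * mgd * sin(th)
    om <- om + h * (t_m + t_g - damping * om) / inertia
    th <- th + h * om
    over_hi <- th > lim_hi
    over_lo <- th < lim_lo
    if (any(over_hi)) {
      th[over_hi] <- lim_hi[over_hi]
      om[over_hi] <- pmin(om[over_hi], 0)
      limit_hit <- TRUE
    }
    if (any(over_lo)) {
      th[over_lo] <- lim_lo[over_lo]
      om[over_lo] <- pmax(om[over_lo], 0)
      limit_hit <- TRUE
    }
  }
  structure(list(
    wrist = wrist_state(th[1] / DEG2RAD, th[2] / DEG2RAD,
                        om[1] / DEG2RAD, om[2] / DEG2RAD,
                        time = w$time + dt),
    actuator_pos = pos,
    cable_force = stats::setNames(f, plant$muscles$name),
    limit_hit = limit_hit
  ), class = "plant_state")
}

#' Noisy sensing of the plant state
#'
#' Virtualizes the motion-capture and load-cell feedback as additive
#' Gaussian noise on the true angles and cable forces.  Identical
#' streams give identical noise sequences.
#'
#' @param state A `plant_state`.
#' @param plant A `wrist_plant`.
#' @param rng An [rng_stream()].
#' @return List with `angles` (named `fe`, `rud`, deg) and `forces`
#'   (named per muscle, N).
#' @export
sense <- function(state, plant, rng) {
  cfg <- plant$config
  ang <- c(fe = state$wrist$theta_fe, rud = state$wrist$theta_rud) +
    rng$rnorm(2L, sd = cfg$angle_noise_sd)
  frc <- state$cable_force + rng$rnorm(6L, sd = cfg$force_noise_sd)
  list(angles = ang, forces = frc)
}

#' Estimate muscle moment arms by tendon-excursion sweeps
#'
#' Sweeps one axis at a time through a range of angles, records the
#' tendon excursion of every muscle against the (noisily) measured
#' angle, and returns the least-squares slope - the signed moment arm -
#' per muscle per axis.
#'
#' @param plant A `wrist_plant`.
#' @param range_deg Sweep range `c(lo, hi)`, deg; must span at least
#'   10 deg.
#' @param n_samples Number of poses per axis, at least 10.
#' @param seed Optional seed for measurement noise (the plant's
#'   `angle_noise_sd`); `NULL` disables noise.
#' @return A 6x2 matrix of moment arms, mm, rows named by muscle and
#'   columns `fe`, `rud`.
#' @export
estimate_moment_arms <- function(plant, range_deg = c(-15, 15),
                                 n_samples = 31, seed = NULL) {
  if (length(range_deg) != 2L || diff(range_deg) < 10) {
    stop("sweep range must span at least 10 degrees")
  }
  if (n_samples < 10L) stop("sweep needs at least 10 samples")
  rng <- if (!is.null(seed)) rng_stream(seed)
  sd_ang <- if (is.null(seed)) 0 else plant$config$angle_noise_sd
  angles <- seq(range_deg[1], range_deg[2], length.out = n_samples)
  out <- matrix(NA_real_, nrow = 6, ncol = 2,
                dimnames = list(plant$muscles$name, c("fe", "rud")))
  for (axis in 1:2) {
    exc <- sapply(angles, function(a) {
      th <- c(0, 0); th[axis] <- a
      tendon_excursion(wrist_state(th[1], th[2]), plant$muscles)
    })  # 6 x n
    meas <- angles + if (sd_ang > 0) rng$rnorm(n_samples, sd = sd_ang) else 0
    x <- meas * DEG2RAD
    for (i in 1:6) {
      out[i, axis] <- stats::coef(stats::lm(exc[i, ] ~ x))[[2]]
    }
  }
  out
}

#' Passive release simulation
#'
#' Pays out all cables (slack) and lets the hand swing freely from an
#' initial pose - the virtual analogue of releasing the rig.  Useful
#' for checking the pendulum physics of the plant.
#'
#' @param plant A `wrist_plant`.
#' @param theta0_fe,theta0_rud Initial angles, deg.
#' @param duration Simulated time, s.
#' @param dt Integration step, s.
#' @return A data.frame with columns `time`, `theta_fe`, `theta_rud`,
#'   `omega_fe`, `omega_rud`, `energy` (total mechanical energy, J,
#'   relative to the hanging-through/neutral datum).
#' @export
simulate_passive <- function(plant, theta0_fe = 5, theta0_rud = 0,
                             duration = 10, dt = 0.001) {
  cfg <- plant$config
  slack <- rep(-1000, 6)  # far more pay-out than any pose requires
  st <- plant_state(plant, wrist_state(theta0_fe, theta0_rud),
                    actuator_pos = stats::setNames(slack, plant$muscles$name))
  n <- ceiling(duration / dt)
  out <- matrix(NA_real_, nrow = n + 1, ncol = 6)
  mgd <- cfg$hand_mass * cfg$gravity * cfg$cog_offset
  gsgn <- if (cfg$orientation == "upward") 1 else -1
  energy <- function(w) {
    ke <- 0.5 * cfg$inertia_fe * (w$omega_fe * DEG2RAD)^2 +
      0.5 * cfg$inertia_rud * (w$omega_rud * DEG2RAD)^2
    # potential: downward has minimum at neutral, upward a maximum
    pe <- -gsgn * mgd * ((1 - cos(w$theta_fe * DEG2RAD)) +
                           (1 - cos(w$theta_rud * DEG2RAD)))
    ke + pe
  }
  out[1, ] <- c(0, theta0_fe, theta0_rud, 0, 0, energy(st$wrist))
  for (i in seq_len(n)) {
    st <- step_dynamics(st, slack, plant, dt)
    w <- st$wrist
    out[i + 1, ] <- c(w$time, w$theta_fe, w$theta_rud,
                      w$omega_fe, w$omega_rud, energy(w))
  }
  as.data.frame(stats::setNames(split(out, col(out)),
    c("time", "theta_fe", "theta_rud", "omega_fe", "omega_rud", "energy")))
}
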