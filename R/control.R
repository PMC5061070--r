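# The four closed-loop strategies.  Each is a pure step function from
# (desired sample, measurements, controller state) to per-muscle
# actuator displacement commands (mm):
#
#   position - one PID per axis on the joint-angle error; the corrective
#     excursion is applied to the ECRB and distributed to the remaining
#     tendons by moment-arm ratios, on top of the nominal excursions of
#     the desired pose.
#   force    - one PI per muscle tracking a prescribed force profile
#     (derivative term forced to zero); its output is an actuator rate,
#     integrated into a displacement command.
#   hybrid   - position control per muscle unless the measured force
#     leaves [F0, Fmax]; then that muscle is handed to a force loop
#     tracking the violated bound, with hysteresis and bumpless
#     transfer.
#   cascade  - per-axis PIDs produce joint torques (+ acceleration
#     feedforward), the QP distributes them onto nonnegative muscle
#     forces with total rho, and per-muscle PI loops track those forces.

MODE_LEVELS <- c("position", "force_low", "force_high", "force_track")

#' Controller configuration
#'
#' @param strategy One of `"position"`, `"force"`, `"hybrid"`,
#'   `"cascade"`.
#' @param axis_gains List with `fe` and `rud` [pid_gains()].  Units:
#'   mm of ECRB-normalized corrective excursion per degree of error for
#'   position/hybrid; N m per degree for cascade.
#' @param force_gains A [pid_gains()] applied to every muscle force
#'   loop (kd is forced to zero); output is an actuator rate, mm/s per
#'   N of force error.
#' @param f0 Lower muscle-force bound, N (hybrid); co-contraction
#'   handle.
#' @param f_max Per-muscle upper bounds, N; `NULL` means specific
#'   tension times PCSA from the muscle table.
#' @param rho Total-force (impedance) constraint for the cascade QP, N;
#'   co-contraction handle.
#' @param ff_gain Scale on the acceleration feedforward `I * accel_d`
#'   (cascade).
#' @param ff_inertia Named `c(fe=, rud=)` inertias used by the
#'   feedforward, kg m^2.
#' @param hysteresis_band Force deadband for hybrid mode switching, N.
#' @param switch_margin_mm Command margin for leaving a force mode, mm.
#' @param force_profiles For the force strategy: a data.frame with a
#'   `time` column and one force column per muscle (`F_FCR`, ...),
#'   typically recorded from a position-control run via
#'   [record_force_profiles()].
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(strategy = c("position", "force", "hybrid",
                                           "cascade"),
                              axis_gains,
                              force_gains = pid_gains(kp = 1, ki = 4),
                              f0 = 10,
                              f_max = NULL,
                              rho = 140,
                              ff_gain = 1,
                              ff_inertia = c(fe = 2e-3, rud = 2e-3),
                              hysteresis_band = 2,
                              switch_margin_mm = 0.3,
                              force_profiles = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(axis_gains), all(c("fe", "rud") %in% names(axis_gains)))
  force_gains$kd <- 0  # derivative on force feedback destabilizes
  if (f0 < 0) stop("f0 must be >= 0")
  if (!is.null(f_max) && any(f0 >= f_max)) {
    stop("invariant violated: f0 must be < min(f_max)")
  }
  if (rho < 6 * f0) {
    warning("rho < 6 * f0: impedance budget below the hybrid force floor")
  }
  structure(list(strategy = strategy, axis_gains = axis_gains,
                 force_gains = force_gains, f0 = f0, f_max = f_max,
                 rho = rho, ff_gain = ff_gain, ff_inertia = ff_inertia,
                 hysteresis_band = hysteresis_band,
                 switch_margin_mm = switch_margin_mm,
                 force_profiles = force_profiles),
            class = "controller_config")
}

#' Fresh controller state
#'
#' @param cc A [controller_config()].
#' @param muscles A `muscle_table`.
#' @return Internal state: axis and per-muscle PID states, force-mode
#'   displacement commands and per-muscle modes.
#' @export
controller_state <- function(cc, muscles) {
  n <- nrow(muscles)
  if (cc$strategy %in% c("position", "hybrid")) {
    R <- moment_arm_matrix(muscles)
    i <- which(muscles$name == "ECRB")
    if (any(abs(R[i, ]) < 1e-9)) {
      stop("ECRB moment arm must be nonzero on both axes for ",
           "excursion distribution")
    }
  }
  list(ax = list(fe = pid_state(), rud = pid_state()),
       force = replicate(n, pid_state(), simplify = FALSE),
       force_hi = replicate(n, pid_state(), simplify = FALSE),
       y_f = stats::setNames(numeric(n), muscles$name),
       z_lo = stats::setNames(numeric(n), muscles$name),
       z_hi = stats::setNames(numeric(n), muscles$name),
       mode = stats::setNames(rep("position", n), muscles$name),
       last_cmd = stats::setNames(numeric(n), muscles$name),
       mode_switches = 0L)
}

# Upper force bounds resolved against the muscle table.
resolved_fmax <- function(cc, muscles) {
  if (is.null(cc$f_max)) muscles$f_max_N else rep_len(cc$f_max, nrow(muscles))
}

# Shared position-control computation: nominal excursions of the
# desired pose plus per-axis PID corrections distributed by moment-arm
# ratios normalized to the ECRB arm on each axis.
position_commands <- function(desired, meas_angles, muscles, cc, st, dt) {
  R <- moment_arm_matrix(muscles)
  i_ecrb <- which(muscles$name == "ECRB")
  y_nom <- drop(R %*% c(desired$theta_fe_d, desired$theta_rud_d)) * DEG2RAD
  e_fe <- desired$theta_fe_d - meas_angles[["fe"]]
  e_rud <- desired$theta_rud_d - meas_angles[["rud"]]
  p_fe <- pid_step(cc$axis_gains$fe, st$ax$fe, e_fe, dt)
  p_rud <- pid_step(cc$axis_gains$rud, st$ax$rud, e_rud, dt)
  dy <- p_fe$output * R[, "fe"] / abs(R[i_ecrb, "fe"]) +
    p_rud$output * R[, "rud"] / abs(R[i_ecrb, "rud"])
  st$ax$fe <- p_fe$state
  st$ax$rud <- p_rud$state
  list(cmd = stats::setNames(y_nom + dy, muscles$name),
       y_nom = stats::setNames(y_nom, muscles$name),
       correction = dy, state = st)
}

#' One step of position control
#'
#' @param desired One row of a [make_trajectory()] frame (as a list).
#' @param meas_angles Named `c(fe=, rud=)` measured angles, deg.
#' @param muscles A `muscle_table`.
#' @param cc A [controller_config()].
#' @param st A [controller_state()].
#' @param dt Control period, s.
#' @return List `output` (fields `actuator_cmd` mm, `desired_forces`,
#'   `mode`) and updated `state`.
#' @export
position_control_step <- function(desired, meas_angles, muscles, cc, st,
                                  dt) {
  pos <- position_commands(desired, meas_angles, muscles, cc, st, dt)
  st <- pos$state
  st$mode[] <- "position"
  st$last_cmd <- pos$cmd
  st$y_f <- pos$cmd  # keep force-mode commands synced (bumpless)
  list(output = list(actuator_cmd = pos$cmd,
                     desired_forces = stats::setNames(rep(NA_real_, nrow(muscles)),
                                                      muscles$name),
                     mode = st$mode),
       state = st)
}

# One PI force-loop update for muscle i: output is an actuator rate
# (mm/s), integrated into the stored displacement command y_f[i].
force_loop_update <- function(i, setpoint, measured, cc, st, dt) {
  p <- pid_step(cc$force_gains, st$force[[i]], setpoint - measured, dt)
  st$force[[i]] <- p$state
  st$y_f[[i]] <- st$y_f[[i]] + dt * p$output
  st
}

#' One step of force control
#'
#' @param desired_forces Named per-muscle force setpoints, N (negative
#'   values are clamped to zero with a warning).
#' @param meas_forces Named per-muscle measured forces, N.
#' @inheritParams position_control_step
#' @return As [position_control_step()]; all modes `force_track`.
#' @export
force_control_step <- function(desired_forces, meas_forces, muscles, cc,
                               st, dt) {
  if (any(desired_forces < 0, na.rm = TRUE)) {
    warning("negative desired force clamped to 0")
    desired_forces <- pmax(desired_forces, 0)
  }
  for (i in seq_len(nrow(muscles))) {
    st <- force_loop_update(i, desired_forces[[i]], meas_forces[[i]], cc,
                            st, dt)
  }
  st$mode[] <- "force_track"
  st$last_cmd <- st$y_f
  list(output = list(actuator_cmd = st$y_f,
                     desired_forces = stats::setNames(desired_forces,
                                                      muscles$name),
                     mode = st$mode),
       state = st)
}

#' One step of hybrid control
#'
#' Position control per muscle unless its measured force leaves the
#' `(F0 + band, Fmax - band)` range; force control to the violated
#' bound is then applied to that muscle.  The hand-off is realized as
#' override (selector) control: a floor force loop tracking `F0` and a
#' ceiling loop tracking `Fmax` run alongside the position command and
#' the selector `min(max(y_pos, y_floor), y_ceil)` picks the governing
#' command per muscle.  An inactive force loop is parked just outside
#' the position command (bumpless transfer), so selection is
#' continuous, upward position corrections always pass through, and
#' the hysteresis band plus parking margin prevent mode chatter.
#'
#' @param meas_forces Named per-muscle measured forces, N.
#' @inheritParams position_control_step
#' @details Force loops ride on the nominal excursion of the desired
#'   pose (`y = y_theta + y_f`), so joint motion is fed forward and the
#'   PI only regulates the tension offset.
#' @export
hybrid_control_step <- function(desired, meas_angles, meas_forces,
                                muscles, cc, st, dt) {
  pos <- position_commands(desired, meas_angles, muscles, cc, st, dt)
  st <- pos$state
  fmax <- resolved_fmax(cc, muscles)
  n <- nrow(muscles)
  desired_forces <- stats::setNames(rep(NA_real_, n), muscles$name)
  cmd <- numeric(n)
  margin <- cc$switch_margin_mm
  for (i in seq_len(n)) {
    dy <- pos$cmd[[i]] - pos$y_nom[[i]]  # position offset from nominal
    f <- meas_forces[[i]]
    # floor loop: active while the force is at/below the band or the
    # floor currently governs; otherwise parked just below position
    if (f < cc$f0 + cc$hysteresis_band || st$z_lo[[i]] > dy) {
      p <- pid_step(cc$force_gains, st$force[[i]], cc$f0 - f, dt)
      st$force[[i]] <- p$state
      # never trail the position command by more than the margin, so a
      # fast force drop is caught without first recovering lost ground
      st$z_lo[[i]] <- max(st$z_lo[[i]] + dt * p$output, dy - margin)
    } else {
      st$z_lo[[i]] <- dy - margin
      st$force[[i]] <- pid_state()
    }
    z_sel <- max(dy, st$z_lo[[i]])
    # ceiling loop, symmetric; parks just above whatever currently
    # governs so an inactive ceiling never caps the floor override
    if (is.finite(fmax[i]) &&
        (f > fmax[i] - cc$hysteresis_band || st$z_hi[[i]] < z_sel)) {
      p <- pid_step(cc$force_gains, st$force_hi[[i]], fmax[i] - f, dt)
      st$force_hi[[i]] <- p$state
      st$z_hi[[i]] <- min(st$z_hi[[i]] + dt * p$output, z_sel + margin)
    } else {
      st$z_hi[[i]] <- z_sel + margin
      st$force_hi[[i]] <- pid_state()
    }
    z <- min(z_sel, st$z_hi[[i]])
    mode <- if (z < z_sel) "force_high" else if (z > dy) "force_low" else "position"
    if (mode == "force_low") desired_forces[[i]] <- cc$f0
    if (mode == "force_high") desired_forces[[i]] <- fmax[i]
    if (mode != st$mode[[i]]) st$mode_switches <- st$mode_switches + 1L
    st$mode[[i]] <- mode
    cmd[i] <- pos$y_nom[[i]] + z
  }
  cmd <- stats::setNames(cmd, muscles$name)
  st$last_cmd <- cmd
  list(output = list(actuator_cmd = cmd, desired_forces = desired_forces,
                     mode = st$mode),
       state = st)
}

#' One step of cascade control
#'
#' Per-axis PIDs on the angle error produce the two joint torques, an
#' acceleration feedforward `ff_gain * I * accel_d` is added, the QP
#' distributes the torques onto nonnegative muscle forces summing to
#' `rho`, and per-muscle PI loops track those forces.
#'
#' @param meas_forces Named per-muscle measured forces, N.
#' @inheritParams position_control_step
#' @return As [position_control_step()]; the output additionally
#'   carries `qp_feasible`.
#' @export
cascade_control_step <- function(desired, meas_angles, meas_forces,
                                 muscles, cc, st, dt) {
  e_fe <- desired$theta_fe_d - meas_angles[["fe"]]
  e_rud <- desired$theta_rud_d - meas_angles[["rud"]]
  p_fe <- pid_step(cc$axis_gains$fe, st$ax$fe, e_fe, dt)
  p_rud <- pid_step(cc$axis_gains$rud, st$ax$rud, e_rud, dt)
  st$ax$fe <- p_fe$state
  st$ax$rud <- p_rud$state
  t_fe <- p_fe$output +
    cc$ff_gain * cc$ff_inertia[["fe"]] * desired$accel_fe_d * DEG2RAD
  t_rud <- p_rud$output +
    cc$ff_gain * cc$ff_inertia[["rud"]] * desired$accel_rud_d * DEG2RAD
  qp <- solve_force_distribution(torque_demand(t_fe, t_rud), muscles,
                                 qp_config(rho = cc$rho))
  fd <- qp$forces
  R <- moment_arm_matrix(muscles)
  y_nom <- drop(R %*% c(desired$theta_fe_d, desired$theta_rud_d)) * DEG2RAD
  for (i in seq_len(nrow(muscles))) {
    st <- force_loop_update(i, fd[[i]], meas_forces[[i]], cc, st, dt)
  }
  st$mode[] <- "force_track"
  cmd <- stats::setNames(y_nom + st$y_f, muscles$name)
  st$last_cmd <- cmd
  list(output = list(actuator_cmd = cmd, desired_forces = fd,
                     mode = st$mode, qp_feasible = qp$feasible),
       state = st)
}
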