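# Closed-loop simulation runner: steps the chosen controller and the
# virtual plant at the control period, records everything, and flags
# runs that hit a joint limit or diverge as not completed.

MODE_CODE <- c(position = 0L, force_low = 1L, force_high = 2L,
               force_track = 3L)

#' Run one closed-loop simulation
#'
#' @param plant A `wrist_plant`.
#' @param cc A [controller_config()]; for the `force` strategy it must
#'   carry `force_profiles`.
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed; drives the sensor-noise substream.
#' @param discard_cycles Settling cycles excluded by the metric
#'   functions downstream (stored with the result).
#' @return An object of class `wrist_sim`: `series` (a data.frame with
#'   time, desired and actual angles, per-muscle forces, desired
#'   forces, commands, and mode codes), `completed`, `spec`, `seed`,
#'   `plant_config`, `controller`, `mode_switches`, `qp_feasible_frac`.
#' @export
run_simulation <- function(plant, cc, spec, seed = 1, discard_cycles = 1) {
  stopifnot(inherits(plant, "wrist_plant"),
            inherits(cc, "controller_config"),
            inherits(spec, "trajectory_spec"))
  cfg <- plant$config
  if (cfg$loop_period > spec$period / 20) {
    stop("loop_period must be at most trajectory period / 20")
  }
  fmax <- resolved_fmax(cc, plant$muscles)
  if (cc$f0 >= min(fmax)) stop("f0 must be below every f_max")
  traj <- make_trajectory(spec, cfg$loop_period, cfg$joint_limits)
  n <- nrow(traj)
  muscles <- plant$muscles
  if (cc$strategy == "force") {
    if (is.null(cc$force_profiles)) {
      stop("force strategy requires force_profiles (see ",
           "record_force_profiles)")
    }
    fp <- interp_profiles(cc$force_profiles, traj$time, muscles$name)
  }
  rng <- rng_stream(derive_seed(seed, "sensor"))
  noise_ang <- matrix(rng$rnorm(2L * n, sd = cfg$angle_noise_sd), nrow = 2L)
  noise_frc <- matrix(rng$rnorm(6L * n, sd = cfg$force_noise_sd), nrow = 6L)
  ps <- plant_state(plant)
  st <- controller_state(cc, muscles)
  rec <- matrix(NA_real_, nrow = n, ncol = 5 + 6 * 4)
  qp_ok <- 0L
  completed <- TRUE
  k_done <- n
  for (k in seq_len(n)) {
    meas_ang <- c(fe = ps$wrist$theta_fe + noise_ang[1, k],
                  rud = ps$wrist$theta_rud + noise_ang[2, k])
    meas_frc <- ps$cable_force + noise_frc[, k]
    desired <- list(theta_fe_d = traj$theta_fe_d[k],
                    theta_rud_d = traj$theta_rud_d[k],
                    accel_fe_d = traj$accel_fe_d[k],
                    accel_rud_d = traj$accel_rud_d[k])
    stp <- switch(cc$strategy,
      position = position_control_step(desired, meas_ang, muscles, cc,
                                       st, cfg$loop_period),
      force = force_control_step(fp[k, ], meas_frc, muscles, cc, st,
                                 cfg$loop_period),
      hybrid = hybrid_control_step(desired, meas_ang, meas_frc, muscles,
                                   cc, st, cfg$loop_period),
      cascade = cascade_control_step(desired, meas_ang, meas_frc,
                                     muscles, cc, st, cfg$loop_period))
    st <- stp$state
    out <- stp$output
    if (!is.null(out$qp_feasible) && out$qp_feasible) qp_ok <- qp_ok + 1L
    ps2 <- tryCatch(step_dynamics(ps, out$actuator_cmd, plant,
                                  cfg$loop_period),
                    error = function(e) NULL)
    if (is.null(ps2)) {
      completed <- FALSE
      k_done <- k - 1L
      break
    }
    ps <- ps2
    if (ps$limit_hit) completed <- FALSE
    rec[k, ] <- c(traj$time[k], traj$theta_fe_d[k], traj$theta_rud_d[k],
                  ps$wrist$theta_fe, ps$wrist$theta_rud,
                  ps$cable_force, out$desired_forces, out$actuator_cmd,
                  MODE_CODE[out$mode])
  }
  series <- as.data.frame(rec[seq_len(k_done), , drop = FALSE])
  names(series) <- c("time", "theta_fe_d", "theta_rud_d", "theta_fe",
                     "theta_rud",
                     paste0("F_", muscles$name),
                     paste0("Fd_", muscles$name),
                     paste0("cmd_", muscles$name),
                     paste0("mode_", muscles$name))
  structure(list(series = series, completed = completed, spec = spec,
                 seed = seed, discard_cycles = discard_cycles,
                 plant_config = cfg,
                 controller = cc[setdiff(names(cc), "force_profiles")],
                 mode_switches = st$mode_switches,
                 qp_feasible_frac = if (cc$strategy == "cascade") {
                   qp_ok / k_done
                 } else NA_real_),
            class = "wrist_sim")
}

#' @export
print.wrist_sim <- function(x, ...) {
  cat("<wrist_sim> ", x$spec$motion, " / ", x$controller$strategy, " / ",
      x$plant_config$orientation, "\n",
      "  ", nrow(x$series), " samples over ",
      round(max(x$series$time, 0), 2), " s; completed: ", x$completed,
      "\n", sep = "")
  invisible(x)
}

# Linear interpolation of recorded force profiles onto the simulation
# clock; constant extrapolation beyond the recording.
interp_profiles <- function(profiles, times, muscle_names) {
  cols <- paste0("F_", muscle_names)
  if (!all(c("time", cols) %in% names(profiles))) {
    stop("force profiles need columns time, ", paste(cols, collapse = ", "))
  }
  out <- sapply(cols, function(cn) {
    stats::approx(profiles$time, profiles[[cn]], xout = times,
                  rule = 2)$y
  })
  colnames(out) <- muscle_names
  out
}

#' Record per-muscle force profiles from a run
#'
#' Captures the actual cable-force time series of a simulation - in
#' practice a position-control run - in the CSV-ready layout that the
#' force strategy replays.
#'
#' @param result A `wrist_sim`.
#' @return A data.frame: `time` plus `F_FCR` ... `F_APL`.
#' @export
record_force_profiles <- function(result) {
  stopifnot(inherits(result, "wrist_sim"))
  cols <- grep("^F_", names(result$series), value = TRUE)
  result$series[, c("time", cols)]
}
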