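# Evaluation metrics: mean absolute kinematic error per axis (after
# discarding settling cycles), error as a percent of the amplitude of
# the moved axis, repeatability as the SD of mean errors across
# repeats, extreme joint angles, and mean muscle forces.

#' Kinematic error metrics of a run
#'
#' @param result A `wrist_sim`.
#' @param discard_cycles Settling cycles to drop before averaging
#'   (default: the value stored with the run).
#' @return A list of class `metrics_report`: `mean_err_fe`,
#'   `mean_err_rud` (deg, mean absolute desired-actual deviation),
#'   `mean_err_inplane` / `mean_err_outplane` (in-plane = the axis with
#'   the largest commanded amplitude), `percent_err` (100 x in-plane
#'   error / in-plane amplitude), extreme angles (deg), `mean_force`
#'   (per muscle, N), `min_force` (per muscle post-settling, N), and
#'   `completed`.
#' @export
kinematic_error <- function(result, discard_cycles = NULL) {
  stopifnot(inherits(result, "wrist_sim"))
  s <- result$series
  if (!nrow(s)) stop("empty simulation series")
  if (is.null(discard_cycles)) discard_cycles <- result$discard_cycles
  spec <- result$spec
  t0 <- discard_cycles * spec$period
  s <- s[s$time >= t0 - 1e-9, , drop = FALSE]
  if (!nrow(s)) stop("no samples left after discarding settling cycles")
  err_fe <- mean(abs(s$theta_fe_d - s$theta_fe))
  err_rud <- mean(abs(s$theta_rud_d - s$theta_rud))
  amps <- c(fe = spec$amp_fe, rud = spec$amp_rud)
  inplane_axis <- if (amps[["fe"]] >= amps[["rud"]]) "fe" else "rud"
  err_in <- if (inplane_axis == "fe") err_fe else err_rud
  err_out <- if (inplane_axis == "fe") err_rud else err_fe
  amp_in <- max(amps)
  fcols <- grep("^F_", names(s), value = TRUE)
  structure(list(
    mean_err_fe = err_fe, mean_err_rud = err_rud,
    mean_err_inplane = err_in, mean_err_outplane = err_out,
    inplane_axis = inplane_axis,
    percent_err = if (amp_in > 0) 100 * err_in / amp_in else NA_real_,
    max_flexion = max(s$theta_fe), max_extension = -min(s$theta_fe),
    max_ulnar = max(s$theta_rud), max_radial = -min(s$theta_rud),
    mean_force = colMeans(s[, fcols, drop = FALSE]),
    min_force = apply(s[, fcols, drop = FALSE], 2, min),
    completed = result$completed
  ), class = "metrics_report")
}

#' Repeatability of a set of repeats
#'
#' Sample standard deviation of the mean in-plane errors across
#' repeated runs of the same condition.
#'
#' @param reports A list of `metrics_report`s (or a numeric vector of
#'   mean in-plane errors).
#' @return Standard deviation, deg.
#' @export
repeatability <- function(reports) {
  errs <- if (is.numeric(reports)) reports else {
    vapply(reports, function(r) r$mean_err_inplane, numeric(1))
  }
  if (length(errs) < 2L) stop("repeatability needs at least 2 repeats")
  stats::sd(errs)
}

#' Co-contraction sweep
#'
#' Runs one full motion per value of the co-contraction handle - `f0`
#' for hybrid control, `rho` for cascade control - and tabulates the
#' per-muscle mean forces (post-settling) together with the kinematic
#' error.
#'
#' @param plant A `wrist_plant`.
#' @param cc A [controller_config()] whose strategy matches `param`.
#' @param spec A [trajectory_spec()].
#' @param param `"f0"` or `"rho"`.
#' @param values Numeric sweep values, N.
#' @param seed Integer seed (each value gets its own substream).
#' @return A data.frame with one row per value: the handle value, mean
#'   force per muscle, `mean_force_overall`, `mean_err_inplane`,
#'   `completed`, `feasible` (fraction of feasible QP ticks for
#'   cascade; `NA` otherwise).
#' @export
co_contraction_sweep <- function(plant, cc, spec, param = c("f0", "rho"),
                                 values, seed = 1) {
  param <- match.arg(param)
  if (param == "f0" && cc$strategy != "hybrid") {
    stop("f0 sweeps apply to hybrid control")
  }
  if (param == "rho" && cc$strategy != "cascade") {
    stop("rho sweeps apply to cascade control")
  }
  rows <- lapply(seq_along(values), function(i) {
    v <- values[i]
    cci <- cc
    cci[[param]] <- v
    res <- run_simulation(plant, cci, spec,
                          seed = derive_seed(seed, paste0("sweep", i)))
    m <- kinematic_error(res)
    out <- c(list(value = v), as.list(m$mean_force),
             list(mean_force_overall = mean(m$mean_force),
                  mean_err_inplane = m$mean_err_inplane,
                  completed = m$completed,
                  feasible = res$qp_feasible_frac))
    as.data.frame(out)
  })
  df <- do.call(rbind, rows)
  names(df)[1] <- param
  df
}

#' Experiment specification
#'
#' @param strategies Character vector of control strategies.
#' @param orientations Character vector of plant orientations.
#' @param motions Character vector of trajectory presets.
#' @param repeats Repeats per condition (>= 1; 5 matches the evaluation
#'   protocol).
#' @param seed Master seed.
#' @param period,n_cycles Trajectory timing.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(strategies = c("hybrid", "cascade"),
                            orientations = c("downward", "upward"),
                            motions = c("FE30", "RUD10"),
                            repeats = 5, seed = 1,
                            period = 4, n_cycles = 3) {
  if (!length(strategies)) stop("at least one strategy is required")
  stopifnot(repeats >= 1,
            all(strategies %in% c("position", "force", "hybrid",
                                  "cascade")),
            all(orientations %in% c("downward", "upward")))
  structure(list(strategies = strategies, orientations = orientations,
                 motions = motions, repeats = as.integer(repeats),
                 seed = seed, period = period, n_cycles = n_cycles),
            class = "experiment_spec")
}

#' Run a full evaluation protocol
#'
#' Crosses strategies x orientations x motions x repeats, recording
#' mean kinematic errors, extreme angles and repeatability for each
#' condition.  Force-control input profiles are recorded from a
#' position-control run of the same motion in the downward orientation
#' and replayed in both orientations.  Failed runs (joint limit or
#' divergence) are kept and flagged, never dropped.
#'
#' @param exp An [experiment_spec()].
#' @param plant_base A `plant_config` (orientation is overridden per
#'   condition).
#' @param muscles A `muscle_table`.
#' @param gains Axis gains as from [tune_axis_gains()] /
#'   [default_gains()].
#' @return List: `runs` (one row per repeat), `summary` (mean +/- SD
#'   per condition, shaped like the headline results table).
#' @export
run_protocol <- function(exp, plant_base = plant_config(),
                         muscles = wrist_muscles(),
                         gains = default_gains()) {
  stopifnot(inherits(exp, "experiment_spec"))
  rows <- list()
  ridx <- 0L
  for (motion in exp$motions) {
    spec <- trajectory_spec(motion, period = exp$period,
                            n_cycles = exp$n_cycles)
    profiles <- NULL
    if ("force" %in% exp$strategies) {
      pl_dn <- wrist_plant(modify_config(plant_base,
                                         orientation = "downward"),
                           muscles)
      rec <- run_simulation(pl_dn,
                            default_controller("position", gains,
                                               plant_base),
                            spec,
                            seed = derive_seed(exp$seed,
                                               paste0("rec", motion)))
      profiles <- record_force_profiles(rec)
    }
    for (strategy in exp$strategies) {
      for (orientation in exp$orientations) {
        plant <- wrist_plant(modify_config(plant_base,
                                           orientation = orientation),
                             muscles)
        cc <- default_controller(strategy, gains, plant_base,
                                 force_profiles = profiles)
        reps <- lapply(seq_len(exp$repeats), function(r) {
          res <- run_simulation(plant, cc, spec,
                                seed = derive_seed(exp$seed,
                                  paste(motion, strategy, orientation, r)))
          m <- kinematic_error(res)
          data.frame(motion = motion, strategy = strategy,
                     orientation = orientation, rep = r,
                     completed = m$completed,
                     mean_err_fe = m$mean_err_fe,
                     mean_err_rud = m$mean_err_rud,
                     mean_err_inplane = m$mean_err_inplane,
                     mean_err_outplane = m$mean_err_outplane,
                     percent_err = m$percent_err,
                     max_flexion = m$max_flexion,
                     max_extension = m$max_extension,
                     max_ulnar = m$max_ulnar,
                     max_radial = m$max_radial)
        })
        ridx <- ridx + 1L
        rows[[ridx]] <- do.call(rbind, reps)
      }
    }
  }
  runs <- do.call(rbind, rows)
  list(runs = runs, summary = summarize_protocol(runs))
}

# Mean +/- SD per motion x strategy x orientation, shaped like the
# headline results table (per-repeat maxima averaged across repeats).
summarize_protocol <- function(runs) {
  key <- interaction(runs$motion, runs$strategy, runs$orientation,
                     drop = TRUE)
  agg <- lapply(split(runs, key), function(g) {
    msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
    data.frame(
      motion = g$motion[1], strategy = g$strategy[1],
      orientation = g$orientation[1],
      n = nrow(g), completed = all(g$completed),
      err_fe_mean = msd(g$mean_err_fe)[1], err_fe_sd = msd(g$mean_err_fe)[2],
      err_rud_mean = msd(g$mean_err_rud)[1], err_rud_sd = msd(g$mean_err_rud)[2],
      repeatability = if (nrow(g) > 1) stats::sd(g$mean_err_inplane) else NA_real_,
      percent_err_mean = mean(g$percent_err),
      max_flexion = mean(g$max_flexion),
      max_extension = mean(g$max_extension),
      max_ulnar = mean(g$max_ulnar),
      max_radial = mean(g$max_radial))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

# Rebuild a plant_config with some fields replaced.
modify_config <- function(cfg, ...) {
  new <- utils::modifyList(unclass(cfg), list(...))
  validate_plant_config(new)
}
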