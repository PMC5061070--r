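# Tuned default gains shipped with the package.  The axis gains come
# from Ziegler-Nichols probes of the default plant (see
# tune_axis_gains(); derate 0.5), the torque and force-loop gains from
# manual tuning against the default plant for low overshoot and smooth
# force profiles.  All are configuration, not physical constants:
# retune after changing the plant.

#' Default tuned controller gains
#'
#' Position/hybrid axis gains (mm of ECRB-normalized corrective
#' excursion per degree), cascade torque gains (N m per degree) and
#' the per-muscle force-loop PI gains (mm/s per N).
#'
#' @return A list with elements `fe`, `rud` (position axis gains),
#'   `torque_fe`, `torque_rud` (cascade), and `force` (muscle PI).
#' @export
default_gains <- function() {
  list(
    fe = pid_gains(kp = 0.0327, ki = 0.862, kd = 6.2e-4,
                   integral_limit = 50, deriv_filter_tau = 0.02),
    rud = pid_gains(kp = 0.0053, ki = 0.140, kd = 1.0e-4,
                    integral_limit = 50, deriv_filter_tau = 0.02),
    torque_fe = pid_gains(kp = 0.08, ki = 0.8, kd = 0.002,
                          integral_limit = 20, deriv_filter_tau = 0.02),
    torque_rud = pid_gains(kp = 0.08, ki = 0.8, kd = 0.002,
                           integral_limit = 20, deriv_filter_tau = 0.02),
    force = pid_gains(kp = 6, ki = 4, integral_limit = 100)
  )
}

#' Build a controller configuration with the shipped defaults
#'
#' @param strategy Control strategy name.
#' @param gains Gain set as returned by [default_gains()] or
#'   [tune_axis_gains()] (the latter supplies only `fe`/`rud`; torque
#'   and force gains fall back to the shipped defaults).
#' @param plant_cfg The plant configuration (for the feedforward
#'   inertias).
#' @param force_profiles Recorded profiles for the force strategy.
#' @param f0,rho Co-contraction handles, N.
#' @return A [controller_config()].
#' @export
default_controller <- function(strategy, gains = default_gains(),
                               plant_cfg = plant_config(),
                               force_profiles = NULL,
                               f0 = 10, rho = 140) {
  base <- default_gains()
  axis <- if (strategy == "cascade") {
    list(fe = if (!is.null(gains$torque_fe)) gains$torque_fe else base$torque_fe,
         rud = if (!is.null(gains$torque_rud)) gains$torque_rud else base$torque_rud)
  } else {
    list(fe = if (!is.null(gains$fe)) gains$fe else base$fe,
         rud = if (!is.null(gains$rud)) gains$rud else base$rud)
  }
  controller_config(
    strategy = strategy,
    axis_gains = axis,
    force_gains = if (!is.null(gains$force)) gains$force else base$force,
    f0 = f0, rho = rho,
    ff_inertia = c(fe = plant_cfg$inertia_fe, rud = plant_cfg$inertia_rud),
    force_profiles = force_profiles)
}
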