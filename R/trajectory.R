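# Desired wrist trajectories.  All motions are sinusoidal with a
# configurable cycle period; presets fix the amplitudes of the planar
# motions (FE-30, RUD-10), the dart thrower's motion (DTM: in-phase
# 30 deg FE with 10 deg RUD, so extension pairs with radial deviation)
# and circumduction (CCD: 20 deg FE with 10 deg RUD in quadrature,
# clockwise or anticlockwise by visiting order).

#' Trajectory specification
#'
#' @param motion One of `"FE30"`, `"RUD10"`, `"DTM"`, `"CCD_CW"`,
#'   `"CCD_ACW"`, `"CUSTOM"`.  Presets fix the amplitudes; `CUSTOM`
#'   uses `amp_fe` and `amp_rud` as in-phase sinusoid amplitudes.
#' @param amp_fe,amp_rud Amplitudes, deg (only for `CUSTOM`).
#' @param period Cycle period, s.
#' @param n_cycles Number of cycles to run.
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(motion = c("FE30", "RUD10", "DTM", "CCD_CW",
                                       "CCD_ACW", "CUSTOM"),
                            amp_fe = 0, amp_rud = 0,
                            period = 4, n_cycles = 3) {
  motion <- match.arg(motion)
  stopifnot(period > 0, n_cycles >= 1)
  amps <- switch(motion,
    FE30 = c(30, 0), RUD10 = c(0, 10), DTM = c(30, 10),
    CCD_CW = c(20, 10), CCD_ACW = c(20, 10),
    CUSTOM = c(amp_fe, amp_rud))
  structure(list(motion = motion, amp_fe = amps[1], amp_rud = amps[2],
                 period = period, n_cycles = n_cycles),
            class = "trajectory_spec")
}

#' Generate the desired-motion samples
#'
#' Planar motions and DTM are in-phase sinusoids starting from neutral;
#' circumduction starts at peak flexion with RUD in quadrature, so
#' clockwise visits flexion, ulnar deviation, extension, radial
#' deviation in order (anticlockwise reverses the RUD sign).
#' Accelerations are analytic, for the cascade feedforward.
#'
#' @param spec A [trajectory_spec()].
#' @param loop_period Sampling period, s; must be at most
#'   `spec$period / 20`.
#' @param joint_limits Optional plant joint limits to validate
#'   amplitudes against.
#' @return A data.frame: `time` (s), `theta_fe_d`, `theta_rud_d` (deg),
#'   `accel_fe_d`, `accel_rud_d` (deg/s^2).
#' @export
make_trajectory <- function(spec, loop_period = 0.005, joint_limits = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (loop_period > spec$period / 20) {
    stop("loop_period must be at most period / 20")
  }
  if (!is.null(joint_limits)) {
    if (spec$amp_fe > max(abs(joint_limits$fe)) ||
        spec$amp_rud > max(abs(joint_limits$rud))) {
      stop("trajectory amplitude exceeds joint limits")
    }
  }
  t <- seq(0, spec$n_cycles * spec$period, by = loop_period)
  w <- 2 * pi / spec$period
  a_fe <- spec$amp_fe
  a_rud <- spec$amp_rud
  if (spec$motion %in% c("CCD_CW", "CCD_ACW")) {
    s_rud <- if (spec$motion == "CCD_CW") 1 else -1
    fe <- a_fe * cos(w * t)
    rud <- s_rud * a_rud * sin(w * t)
    acc_fe <- -a_fe * w^2 * cos(w * t)
    acc_rud <- -s_rud * a_rud * w^2 * sin(w * t)
  } else {
    fe <- a_fe * sin(w * t)
    rud <- a_rud * sin(w * t)
    acc_fe <- -a_fe * w^2 * sin(w * t)
    acc_rud <- -a_rud * w^2 * sin(w * t)
  }
  data.frame(time = t, theta_fe_d = fe, theta_rud_d = rud,
             accel_fe_d = acc_fe, accel_rud_d = acc_rud)
}
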