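# Discrete PID with trapezoidal integration, anti-windup clamping and a
# first-order low-pass filter on the derivative term.  One instance per
# controlled axis (position, torque) or per muscle (force; kd = 0).

#' PID gains
#'
#' @param kp,ki,kd Proportional, integral, derivative gains (>= 0).
#' @param integral_limit Anti-windup clamp on the integral accumulator
#'   (in error x time units); must be > 0.
#' @param deriv_filter_tau Time constant of the first-order filter
#'   applied to the error before differentiation, s (0 = no filter).
#' @return List of class `pid_gains`.
#' @export
pid_gains <- function(kp, ki = 0, kd = 0, integral_limit = 1e6,
                      deriv_filter_tau = 0) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, integral_limit > 0,
            deriv_filter_tau >= 0)
  structure(list(kp = kp, ki = ki, kd = kd,
                 integral_limit = integral_limit,
                 deriv_filter_tau = deriv_filter_tau),
            class = "pid_gains")
}

#' Fresh PID state
#' @return List with zero integral and no derivative history.
#' @export
pid_state <- function() {
  list(integral = 0, err_filt = NA_real_, err_raw_prev = NA_real_)
}

#' One PID update
#'
#' `output = kp e + ki * I(e) + kd * d(e_filtered)/dt` with the
#' integral accumulated trapezoidally and clamped at
#' `+/- integral_limit`.
#'
#' @param gains A [pid_gains()].
#' @param st A [pid_state()].
#' @param error Current error sample.
#' @param dt Time since the previous sample, s (> 0).
#' @return List `output` and updated `state`.
#' @export
pid_step <- function(gains, st, error, dt) {
  if (!is.finite(error)) stop("PID error must be finite")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  prev_raw <- if (is.na(st$err_raw_prev)) error else st$err_raw_prev
  integral <- st$integral + dt * (error + prev_raw) / 2
  integral <- min(max(integral, -gains$integral_limit), gains$integral_limit)
  tau <- gains$deriv_filter_tau
  alpha <- if (tau > 0) dt / (tau + dt) else 1
  filt_prev <- if (is.na(st$err_filt)) error else st$err_filt
  filt <- filt_prev + alpha * (error - filt_prev)
  deriv <- if (is.na(st$err_filt)) 0 else (filt - st$err_filt) / dt
  out <- gains$kp * error + gains$ki * integral + gains$kd * deriv
  list(output = out,
       state = list(integral = integral, err_filt = filt,
                    err_raw_prev = error))
}
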