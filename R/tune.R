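# Ziegler-Nichols ultimate-gain tuning.  A proportional-only probe of
# the closed loop is run at increasing gain until the step response
# shows a sustained constant-amplitude oscillation; the gain at that
# boundary is the ultimate gain K_u and the oscillation period T_u.
# Classic table gains are then kp = 0.6 K_u, ki = 2 kp / T_u,
# kd = kp T_u / 8.

# Peak analysis of a probe response: returns the geometric-mean decay
# ratio of successive oscillation peaks (about the late-response mean)
# and the mean peak-to-peak period.  ratio < 1: decaying; > 1 growing.
analyze_oscillation <- function(time, y, skip_frac = 0.2,
                                setpoint = NULL, blowup = NULL) {
  n <- length(y)
  # a response that runs away from the setpoint by far more than the
  # commanded step is unstable, whatever its peak pattern looks like
  # (saturation at the joint limits masquerades as constant amplitude)
  if (!is.null(setpoint) && !is.null(blowup) &&
      max(abs(y - setpoint)) > blowup) {
    return(list(ratio = Inf, period = NA_real_, n_peaks = 0L))
  }
  i0 <- max(2L, floor(skip_frac * n))
  t <- time[i0:n]
  x <- y[i0:n] - mean(y[max(1L, n - floor(n / 3)):n])
  up <- which(diff(sign(diff(x))) < 0) + 1L  # local maxima
  up <- up[x[up] > 1e-9]
  if (length(up) < 3L) {
    return(list(ratio = 0, period = NA_real_, n_peaks = length(up)))
  }
  amps <- x[up]
  ratios <- amps[-1] / amps[-length(amps)]
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  if (!length(ratios)) {
    return(list(ratio = 0, period = NA_real_, n_peaks = length(up)))
  }
  list(ratio = exp(mean(log(ratios))),
       period = mean(diff(t[up])),
       n_peaks = length(up))
}

#' Ziegler-Nichols ultimate-gain tuning
#'
#' @param probe A function of a single proportional gain `kp` returning
#'   the closed-loop step response as a list/data.frame with elements
#'   `time` and `y` (the controlled output).  See
#'   [make_position_probe()] for the wrist plant's probe.
#' @param kp_init Initial proportional gain for the search.
#' @param kp_max Upper limit of the gain search; if no sustained
#'   oscillation is found below it, tuning fails with a diagnostic.
#' @param ratio_tol Acceptable deviation of the peak decay ratio from 1
#'   at the ultimate gain.
#' @param max_bisect Bisection iteration cap.
#' @return List: `K_u`, `T_u`, `gains` (a [pid_gains()] from the
#'   classic table), and the final probe `analysis`.
#' @export
ziegler_nichols_tune <- function(probe, kp_init = 0.05, kp_max = 1e4,
                                 ratio_tol = 0.05, max_bisect = 30L) {
  eval_kp <- function(kp) {
    r <- probe(kp)
    sp <- if (is.null(r$setpoint)) NULL else r$setpoint
    analyze_oscillation(r$time, r$y, setpoint = sp,
                        blowup = if (is.null(sp)) NULL else 10 * abs(sp))
  }
  # bracket: grow kp until the oscillation stops decaying
  kp_lo <- NA_real_
  kp_hi <- NA_real_
  kp <- kp_init
  a <- NULL
  while (kp <= kp_max) {
    a <- eval_kp(kp)
    if (a$ratio >= 1) {
      kp_hi <- kp
      break
    }
    kp_lo <- kp
    kp <- kp * 2
  }
  if (is.na(kp_hi)) {
    stop("no sustained oscillation up to kp = ", kp_max,
         "; last decay ratio ", signif(if (is.null(a)) NA else a$ratio, 3),
         " - the loop appears overdamped in the search range")
  }
  if (is.na(kp_lo)) kp_lo <- kp_hi / 4
  # bisect on the decay ratio
  for (it in seq_len(max_bisect)) {
    kp <- sqrt(kp_lo * kp_hi)
    a <- eval_kp(kp)
    if (abs(a$ratio - 1) <= ratio_tol && !is.na(a$period)) break
    if (a$ratio < 1) kp_lo <- kp else kp_hi <- kp
    if (kp_hi / kp_lo < 1.001) break
  }
  if (is.na(a$period)) {
    # measure the period just inside the stable side of the boundary
    kp <- kp_lo
    a <- eval_kp(kp)
  }
  if (is.na(a$period)) {
    stop("oscillation period could not be measured at the ultimate gain")
  }
  K_u <- kp
  T_u <- a$period
  kp_zn <- 0.6 * K_u
  list(K_u = K_u, T_u = T_u,
       gains = pid_gains(kp = kp_zn, ki = 2 * kp_zn / T_u,
                         kd = kp_zn * T_u / 8),
       analysis = a)
}

#' Proportional-only probe of the wrist position loop
#'
#' Builds the closure used by [ziegler_nichols_tune()] for one wrist
#' axis: a small step is commanded under proportional-only position
#' control (noise-free feedback, so the probe is deterministic) and the
#' true angle of the probed axis is returned.
#'
#' @param plant A `wrist_plant`; probing is done in the configured
#'   orientation (use downward: the plant is open-loop stable there).
#' @param axis `"fe"` or `"rud"`.
#' @param step_deg Step amplitude, deg.
#' @param duration Probe duration, s.
#' @return A function `kp -> list(time, y, setpoint)`.
#' @export
make_position_probe <- function(plant, axis = c("fe", "rud"),
                                step_deg = 2, duration = 8) {
  axis <- match.arg(axis)
  force(plant)
  function(kp) {
    cc <- controller_config(
      strategy = "position",
      axis_gains = list(
        fe = pid_gains(kp = if (axis == "fe") kp else 0),
        rud = pid_gains(kp = if (axis == "rud") kp else 0)))
    st <- controller_state(cc, plant$muscles)
    ps <- plant_state(plant)
    dt <- plant$config$loop_period
    n <- ceiling(duration / dt)
    y <- numeric(n)
    tm <- numeric(n)
    desired <- list(theta_fe_d = if (axis == "fe") step_deg else 0,
                    theta_rud_d = if (axis == "rud") step_deg else 0)
    for (k in seq_len(n)) {
      meas <- c(fe = ps$wrist$theta_fe, rud = ps$wrist$theta_rud)
      stp <- position_control_step(desired, meas, plant$muscles, cc, st, dt)
      st <- stp$state
      ps <- step_dynamics(ps, stp$output$actuator_cmd, plant, dt)
      y[k] <- if (axis == "fe") ps$wrist$theta_fe else ps$wrist$theta_rud
      tm[k] <- ps$wrist$time
    }
    list(time = tm, y = y, setpoint = step_deg)
  }
}

#' Tuned default axis gains for the wrist position loop
#'
#' Runs [ziegler_nichols_tune()] on both axes of the given plant and
#' applies the documented manual derating (classic Ziegler-Nichols
#' gains are intentionally aggressive; the derating trades response
#' speed for low overshoot): kp and ki scaled by `derate`, kd kept.
#' The derivative term acts on a filtered error (tau = 0.02 s) to
#' tolerate motion-capture noise, and the integral is clamped.
#'
#' @param plant A `wrist_plant` (downward orientation recommended for
#'   probing).
#' @param derate Multiplier on the classic kp and ki.
#' @return List with `fe` and `rud` [pid_gains()] plus the raw `K_u`,
#'   `T_u` per axis.
#' @export
tune_axis_gains <- function(plant, derate = 0.5) {
  out <- list()
  for (axis in c("fe", "rud")) {
    zn <- ziegler_nichols_tune(make_position_probe(plant, axis))
    g <- zn$gains
    out[[axis]] <- pid_gains(kp = derate * g$kp, ki = derate * g$ki,
                             kd = g$kd, integral_limit = 50,
                             deriv_filter_tau = 0.02)
    out[[paste0(axis, "_zn")]] <- list(K_u = zn$K_u, T_u = zn$T_u)
  }
  out
}
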