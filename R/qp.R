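# Redundant muscle-force distribution.
#
# The wrist has six muscles and two torque axes, so a demanded joint
# torque admits infinitely many force distributions.  The distribution
# used by cascade control minimizes the sum of squared muscle stresses,
#     minimize   sum_i (F_i / A_i)^2
#     subject to sum_i r_ij F_i = T_j   (j = FE, RUD)
#                sum_i F_i       = rho  (impedance / co-contraction)
#                F_i >= 0,
# a strictly convex quadratic program solved here with a primal
# active-set method on the nonnegativity bounds; tiny (6 variables,
# 3 equalities) so it can run every control tick.

#' QP configuration
#'
#' @param rho Total muscle force (impedance), N; controls
#'   co-contraction. Default 140 N.
#' @param tol KKT/feasibility tolerance (dimensionless).
#' @param max_iter Active-set iteration cap.
#' @param enforce_fmax If `TRUE`, additionally clamp each force at the
#'   muscle's `f_max_N` (off by default: upper bounds belong to hybrid
#'   control, not to this distribution).
#' @return A list of class `qp_config`.
#' @export
qp_config <- function(rho = 140, tol = 1e-9, max_iter = 100L,
                      enforce_fmax = FALSE) {
  stopifnot(rho > 0, tol > 0, max_iter >= 1)
  structure(list(rho = rho, tol = tol, max_iter = as.integer(max_iter),
                 enforce_fmax = enforce_fmax),
            class = "qp_config")
}

# Light validation for the QP routines: any number of muscles (the
# enumeration oracle is exponential, so it caps n at 12), positive
# PCSAs, finite arms.
check_qp_muscles <- function(muscles) {
  need <- c("name", "pcsa_cm2", "r_fe_mm", "r_rud_mm")
  if (!is.data.frame(muscles) || !all(need %in% names(muscles))) {
    stop("muscle table needs columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(muscles$pcsa_cm2)) || any(muscles$pcsa_cm2 <= 0)) {
    stop("pcsa_cm2 must be finite and > 0")
  }
  if (any(!is.finite(muscles$r_fe_mm)) || any(!is.finite(muscles$r_rud_mm))) {
    stop("moment arms must be finite")
  }
  muscles
}

# Build the 3 x n equality-constraint matrix (rows: FE torque, RUD
# torque in N m with arms converted mm -> m, total force) and RHS.
# Torque rows with all-zero coefficients are dropped when their demand
# is zero (redundant) and flagged impossible otherwise.
qp_constraints <- function(demand, muscles, rho) {
  R <- moment_arm_matrix(muscles) / 1000  # m
  C <- rbind(fe = R[, "fe"], rud = R[, "rud"], rho = rep(1, nrow(muscles)))
  d <- c(fe = demand[["t_fe"]], rud = demand[["t_rud"]], rho = rho)
  zero_row <- rowSums(abs(C)) < 1e-15
  impossible <- zero_row & abs(d) > 1e-12
  list(C = C[!zero_row, , drop = FALSE], d = d[!zero_row],
       impossible = any(impossible))
}

#' Torque demand
#'
#' @param t_fe,t_rud Demanded torques about FE and RUD, N m.
#' @return Named list of class `torque_demand`.
#' @export
torque_demand <- function(t_fe, t_rud) {
  stopifnot(is.finite(t_fe), is.finite(t_rud))
  structure(list(t_fe = t_fe, t_rud = t_rud), class = "torque_demand")
}

# Solve the equality-constrained subproblem with variables in `free`
# unrestricted and the rest fixed at 0:
#   min 1/2 F' Q F  s.t.  C_S F_S = d,   Q = diag(2/A^2).
# Returns F_S and the equality multipliers nu, or NULL if the reduced
# system is singular (the active set cannot satisfy the equalities).
solve_eq_qp <- function(C, d, qinv, free) {
  Cs <- C[, free, drop = FALSE]
  M <- Cs %*% (qinv[free] * t(Cs))
  nu <- tryCatch(solve(M, d), error = function(e) NULL)
  if (is.null(nu)) return(NULL)
  list(f = qinv[free] * drop(crossprod(Cs, nu)), nu = nu)
}

#' Distribute a torque demand onto nonnegative muscle forces
#'
#' Solves the stress-minimizing force-distribution QP (see the package
#' vignette) with a primal active-set method.  Strict convexity makes
#' the minimizer unique, so identical inputs give identical outputs.
#'
#' If the impedance constraint `sum F = rho` is incompatible with the
#' torque equalities under `F >= 0`, the torque equalities take
#' priority: the problem is re-solved with the impedance row dropped,
#' the result is returned with `feasible = FALSE`, and the caller can
#' keep running (a physical rig cannot simply stop mid-motion).
#'
#' @param demand A [torque_demand()].
#' @param muscles A `muscle_table`.
#' @param qp A [qp_config()].
#' @return A list of class `qp_solution`: `forces` (named, N),
#'   `objective` (`sum (F_i/A_i)^2`), `active_set` (muscles clamped at
#'   zero), `feasible`, `residuals` (the three equality residuals),
#'   `iterations`, and `rho_dropped`.
#' @export
solve_force_distribution <- function(demand, muscles, qp = qp_config()) {
  muscles <- check_qp_muscles(muscles)
  con <- qp_constraints(demand, muscles, qp$rho)
  if (con$impossible) {
    return(qp_solution(numeric(nrow(muscles)), muscles, con, qp,
                       feasible = FALSE, iterations = 0L,
                       rho_dropped = FALSE))
  }
  sol <- active_set_qp(con$C, con$d, muscles, qp)
  if (!sol$ok) {
    # torque priority: drop the impedance row and re-solve
    keep <- rownames(con$C) != "rho"
    relaxed <- active_set_qp(con$C[keep, , drop = FALSE], con$d[keep],
                             muscles, qp)
    f <- if (relaxed$ok) relaxed$forces else numeric(nrow(muscles))
    return(qp_solution(f, muscles, con, qp, feasible = FALSE,
                       iterations = sol$iterations + relaxed$iterations,
                       rho_dropped = TRUE))
  }
  qp_solution(sol$forces, muscles, con, qp, feasible = TRUE,
              iterations = sol$iterations, rho_dropped = FALSE)
}

qp_solution <- function(forces, muscles, con, qp, feasible, iterations,
                        rho_dropped) {
  res <- drop(con$C %*% forces) - con$d
  structure(list(
    forces = stats::setNames(forces, muscles$name),
    objective = sum((forces / muscles$pcsa_cm2)^2),
    active_set = muscles$name[forces <= qp$tol * max(1, qp$rho)],
    feasible = feasible,
    residuals = res,
    iterations = iterations,
    rho_dropped = rho_dropped
  ), class = "qp_solution")
}

# Primal active-set loop over the nonnegativity bounds.  `C` may have 2
# rows (torque only) or 3 (torque + impedance).  Optionally also treats
# f_max as upper bounds.  Returns ok = FALSE when no active set can
# satisfy the equalities.
active_set_qp <- function(C, d, muscles, qp) {
  n <- ncol(C)
  m <- nrow(C)
  qinv <- muscles$pcsa_cm2^2 / 2      # Q = diag(2/A^2)
  fmax <- if (qp$enforce_fmax) muscles$f_max_N else rep(Inf, n)
  at_upper <- rep(FALSE, n)
  free <- rep(TRUE, n)
  scale <- max(1, abs(d))
  iter <- 0L
  while (iter < qp$max_iter) {
    iter <- iter + 1L
    idx <- which(free)
    if (length(idx) < m) return(list(ok = FALSE, iterations = iter))
    dd <- d - if (any(at_upper)) {
      drop(C[, at_upper, drop = FALSE] %*% fmax[at_upper])
    } else 0
    eq <- solve_eq_qp(C, dd, qinv, idx)
    if (is.null(eq)) return(list(ok = FALSE, iterations = iter))
    f <- numeric(n)
    f[at_upper] <- fmax[at_upper]
    f[idx] <- eq$f
    tol <- qp$tol * scale
    viol_lo <- idx[eq$f < -tol]
    viol_hi <- idx[eq$f > fmax[idx] + tol]
    if (length(viol_lo) || length(viol_hi)) {
      # clamp the worst violator and iterate
      cand <- c(viol_lo, viol_hi)
      excess <- c(-eq$f[match(viol_lo, idx)],
                  (eq$f - fmax[idx])[match(viol_hi, idx)])
      worst <- cand[which.max(excess)]
      free[worst] <- FALSE
      at_upper[worst] <- worst %in% viol_hi
      next
    }
    # dual check on clamped variables: release if profitable
    clamped <- which(!free)
    if (length(clamped)) {
      grad <- (2 / muscles$pcsa_cm2^2) * f - drop(crossprod(C, eq$nu))
      mu <- ifelse(at_upper[clamped], -grad[clamped], grad[clamped])
      bad <- clamped[mu < -tol]
      if (length(bad)) {
        rel <- bad[which.min(mu[match(bad, clamped)])]
        free[rel] <- TRUE
        at_upper[rel] <- FALSE
        next
      }
    }
    return(list(ok = TRUE, forces = f, iterations = iter))
  }
  list(ok = FALSE, iterations = iter)
}

#' Exhaustive active-set enumeration oracle
#'
#' Independent verification route for [solve_force_distribution()]:
#' enumerates every subset of muscles clamped at zero, solves each
#' equality-constrained QP directly through its augmented KKT linear
#' system, keeps the primal-feasible candidates and returns the one
#' with minimum objective.  Exponential in the number of muscles, so
#' restricted to n <= 12.
#'
#' @inheritParams solve_force_distribution
#' @return A `qp_solution` (with `feasible = FALSE` and zero forces if
#'   no subset is feasible).
#' @export
oracle_enumerate <- function(demand, muscles, qp = qp_config()) {
  muscles <- check_qp_muscles(muscles)
  n <- nrow(muscles)
  if (n > 12L) stop("oracle is exponential; n must be <= 12")
  con <- qp_constraints(demand, muscles, qp$rho)
  if (con$impossible) {
    return(qp_solution(numeric(n), muscles, con, qp, feasible = FALSE,
                       iterations = 0L, rho_dropped = FALSE))
  }
  C <- con$C
  d <- con$d
  m <- nrow(C)
  q <- 2 / muscles$pcsa_cm2^2
  tol <- qp$tol * max(1, abs(d))
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- !as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    nf <- sum(free)
    if (nf < m) next
    # augmented KKT: [diag(q_S) C_S'; C_S 0] [F; -nu] = [0; d]
    K <- rbind(cbind(diag(q[free], nf), t(C[, free, drop = FALSE])),
               cbind(C[, free, drop = FALSE], matrix(0, m, m)))
    sol <- tryCatch(solve(K, c(numeric(nf), d)), error = function(e) NULL)
    if (is.null(sol)) next
    f <- numeric(n)
    f[free] <- sol[seq_len(nf)]
    if (any(f < -tol)) next
    f <- pmax(f, 0)
    if (max(abs(drop(C %*% f) - d)) > 10 * tol) next
    obj <- sum((f / muscles$pcsa_cm2)^2)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- f
    }
  }
  if (is.null(best)) {
    return(qp_solution(numeric(n), muscles, con, qp, feasible = FALSE,
                       iterations = 2^n, rho_dropped = FALSE))
  }
  qp_solution(best, muscles, con, qp, feasible = TRUE,
              iterations = 2^n, rho_dropped = FALSE)
}

#' Feasibility of an impedance level for a torque demand
#'
#' Computes the minimum total muscle force able to realize the demanded
#' torques with nonnegative forces (a tiny linear program, solved by
#' vertex enumeration), and whether the requested `rho` is achievable.
#' With `f_max` supplied, also computes the maximum achievable total.
#'
#' @param demand A [torque_demand()].
#' @param muscles A `muscle_table`.
#' @param rho Requested total force, N.
#' @param f_max Optional per-muscle upper bounds, N.
#' @return List: `min_total_force`, `max_total_force` (Inf without
#'   bounds), `rho_feasible`, `reason`.
#' @export
feasibility_check <- function(demand, muscles, rho, f_max = NULL) {
  muscles <- check_qp_muscles(muscles)
  R <- moment_arm_matrix(muscles) / 1000
  A <- rbind(R[, "fe"], R[, "rud"])  # 2 x 6
  b <- c(demand[["t_fe"]], demand[["t_rud"]])
  n <- ncol(A)
  ub <- if (is.null(f_max)) rep(Inf, n) else f_max
  tol <- 1e-9 * max(1, abs(b))
  best_min <- Inf
  best_max <- -Inf
  # vertices: two variables free (solve the 2x2 equalities), the rest
  # at a bound (0, or f_max when finite)
  pairs <- utils::combn(n, 2)
  for (p in seq_len(ncol(pairs))) {
    ij <- pairs[, p]
    fixed <- setdiff(seq_len(n), ij)
    patterns <- if (is.null(f_max)) {
      matrix(0, nrow = 1, ncol = length(fixed))
    } else {
      as.matrix(expand.grid(rep(list(c(0, 1)), length(fixed))))
    }
    M <- A[, ij, drop = FALSE]
    detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(detM) < 1e-14) next
    for (r in seq_len(nrow(patterns))) {
      f <- numeric(n)
      f[fixed] <- ifelse(patterns[r, ] > 0, ub[fixed], 0)
      if (any(!is.finite(f))) next
      rhs <- b - drop(A[, fixed, drop = FALSE] %*% f[fixed])
      f[ij] <- c(M[2, 2] * rhs[1] - M[1, 2] * rhs[2],
                 -M[2, 1] * rhs[1] + M[1, 1] * rhs[2]) / detM
      if (any(f < -tol) || any(f > ub + tol)) next
      tot <- sum(f)
      best_min <- min(best_min, tot)
      best_max <- max(best_max, tot)
    }
  }
  # zero-force vertex (demand exactly zero)
  if (max(abs(b)) <= tol) {
    best_min <- 0
    best_max <- max(best_max, 0)
  }
  if (!is.finite(best_min)) {
    return(list(min_total_force = NA_real_, max_total_force = NA_real_,
                rho_feasible = FALSE,
                reason = "torque demand unachievable with nonnegative forces"))
  }
  max_total <- if (is.null(f_max)) Inf else best_max
  ok <- rho >= best_min - tol && rho <= max_total + tol
  list(min_total_force = max(0, best_min), max_total_force = max_total,
       rho_feasible = ok,
       reason = if (ok) "ok" else if (rho < best_min) {
         "rho below the minimum total force required by the torque demand"
       } else "rho above the maximum total force permitted by f_max")
}
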