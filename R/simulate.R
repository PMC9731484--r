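#' Simulate the arm to a steady-state cycle
#'
#' Integrates the rigid-body dynamics under the impedance controller from
#' rest at the configuration whose endpoint lies on the reference orbit at
#' `t = 0` (elbow-up inverse-kinematics branch), discards transient cycles
#' until the endpoint path repeats, and returns exactly one period sampled
#' on a regular grid.
#'
#' Integration uses an adaptive Dormand-Prince Runge-Kutta scheme
#' (`deSolve::ode`, method `"ode45"`) with dense output resampled to the
#' output grid. Convergence is declared when the maximum endpoint distance
#' between corresponding samples of consecutive cycles drops below `tol`;
#' the returned cycle spans `[0, period]` inclusive, so its first and last
#' samples coincide within `tol` (a closed path).
#'
#' @param params An [arm_params()] object.
#' @param ctrl A [controller_params()] object. The reference circle must lie
#'   strictly inside the arm's reachable annulus.
#' @param dt_out Output sample spacing (s); default 1 ms.
#' @param max_cycles Maximum number of cycles to integrate before giving up
#'   (error on non-convergence).
#' @param tol Convergence tolerance on the endpoint path (m).
#' @param extra_cycles Integrate this many additional cycles after
#'   convergence before returning (used to verify that the limit cycle does
#'   not depend on the transient cap).
#' @param rtol,atol Relative and absolute integrator tolerances.
#'
#' @return A tibble of class `arm_trajectory` with columns `t`, `q1`, `q2`,
#'   `qd1`, `qd2` (joint states), `x`, `y`, `xd`, `yd` (endpoint kinematics,
#'   derived through the forward kinematics and Jacobian). Attributes:
#'   `params`, `ctrl`, `E`, `period`, and `meta` (cycles integrated,
#'   convergence deltas).
#' @examples
#' \donttest{
#' traj <- simulate_steady_cycle(arm_params(), controller_params(E = 0))
#' attr(traj, "meta")$cycles
#' }
#' @export
simulate_steady_cycle <- function(params = arm_params(),
                                  ctrl = controller_params(),
                                  dt_out = 1e-3,
                                  max_cycles = 20,
                                  tol = 1e-4,
                                  extra_cycles = 0,
                                  rtol = 1e-8,
                                  atol = 1e-10) {
  d <- sqrt(sum(ctrl$circle_center^2))
  reach_lo <- abs(params$l1 - params$l2)
  reach_hi <- params$l1 + params$l2
  if (d + ctrl$circle_radius >= reach_hi || d - ctrl$circle_radius <= reach_lo) {
    stop("reference circle is not strictly inside the reachable annulus [",
         signif(reach_lo, 3), ", ", signif(reach_hi, 3), "] m")
  }

  rhs <- make_arm_rhs(params, ctrl)
  ref0 <- reference_endpoint(ctrl, 0)
  q0 <- inverse_kinematics(params, c(ref0$xr, ref0$yr))
  y0 <- c(q0, 0, 0)

  period <- ctrl$period
  tgrid <- seq(0, period, by = dt_out)
  n <- length(tgrid)

  prev_xy <- NULL
  deltas <- numeric(0)
  converged <- FALSE
  sol <- NULL
  cycles <- 0L
  remaining_extra <- extra_cycles
  for (cyc in seq_len(max_cycles + extra_cycles)) {
    sol <- deSolve::ode(y0, tgrid, rhs, parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    cycles <- cyc
    fk <- forward_kinematics(params, sol[, 2:3])
    xy <- cbind(fk$x, fk$y)
    if (!is.null(prev_xy)) {
      delta <- max(sqrt(rowSums((xy - prev_xy)^2)))
      deltas <- c(deltas, delta)
      if (!converged && delta < tol) converged <- TRUE
      if (converged) {
        if (remaining_extra <= 0) break
        remaining_extra <- remaining_extra - 1L
      }
    }
    prev_xy <- xy
    y0 <- sol[n, 2:5]
  }
  if (!converged) {
    stop("steady cycle did not converge within ", max_cycles,
         " cycles (last cycle-to-cycle endpoint delta: ",
         signif(utils::tail(deltas, 1), 3), " m)")
  }

  q <- sol[, 2:3]
  qd <- sol[, 4:5]
  fk <- forward_kinematics(params, q)
  xd <- yd <- numeric(n)
  for (i in seq_len(n)) {
    v <- arm_jacobian(params, q[i, ]) %*% qd[i, ]
    xd[i] <- v[1]; yd[i] <- v[2]
  }
  out <- tibble::tibble(
    t = tgrid,
    q1 = q[, 1], q2 = q[, 2], qd1 = qd[, 1], qd2 = qd[, 2],
    x = fk$x, y = fk$y, xd = xd, yd = yd
  )
  new_arm_trajectory(out, params, ctrl,
                     meta = list(cycles = cycles, converged = TRUE,
                                 deltas = deltas, tol = tol, dt_out = dt_out))
}

new_arm_trajectory <- function(df, params, ctrl, meta = list(),
                               condition = NULL) {
  structure(
    df,
    params = params, ctrl = ctrl, E = ctrl$E, period = ctrl$period,
    meta = meta, condition = condition,
    class = c("arm_trajectory", class(tibble::tibble()))
  )
}

# Scalarized right-hand side of the state equations, closed over the
# parameter values; kept free of per-call allocation for integrator speed.
# Tests verify it against the modular dynamics_terms()/controller_torque().
make_arm_rhs <- function(params, ctrl) {
  l1 <- params$l1; l2 <- params$l2
  m1 <- params$m1; m2 <- params$m2
  lc1 <- params$lc1; lc2 <- params$lc2
  I1 <- params$I1; I2 <- params$I2
  gx <- params$g_mag * params$g_dir[1]
  gy <- params$g_mag * params$g_dir[2]
  Kx11 <- ctrl$Kx[1, 1]; Kx12 <- ctrl$Kx[1, 2]; Kx22 <- ctrl$Kx[2, 2]
  Bx11 <- ctrl$Bx[1, 1]; Bx12 <- ctrl$Bx[1, 2]; Bx22 <- ctrl$Bx[2, 2]
  Kq11 <- ctrl$Kq[1, 1]; Kq12 <- ctrl$Kq[1, 2]; Kq22 <- ctrl$Kq[2, 2]
  qr1 <- ctrl$qr[1]; qr2 <- ctrl$qr[2]
  cx <- ctrl$circle_center[1]; cy <- ctrl$circle_center[2]
  r <- ctrl$circle_radius; om <- ctrl$omega; ph0 <- ctrl$phase0
  a <- m2 * l1 * lc2
  M22 <- m2 * lc2^2 + I2
  M11_0 <- m1 * lc1^2 + I1 + m2 * (l1^2 + lc2^2) + I2

  function(t, y, parms) {
    q1 <- y[1]; q2 <- y[2]; qd1 <- y[3]; qd2 <- y[4]
    c1 <- cos(q1); s1 <- sin(q1)
    c12 <- cos(q1 + q2); s12 <- sin(q1 + q2)
    c2 <- cos(q2); s2 <- sin(q2)
    M11 <- M11_0 + 2 * a * c2
    M12 <- M22 + a * c2
    h <- a * s2
    Cq1 <- -h * qd2 * qd1 - h * (qd1 + qd2) * qd2
    Cq2 <- h * qd1 * qd1
    g1 <- -m1 * (gx * (-lc1 * s1) + gy * (lc1 * c1)) -
      m2 * (gx * (-l1 * s1 - lc2 * s12) + gy * (l1 * c1 + lc2 * c12))
    g2 <- -m2 * (gx * (-lc2 * s12) + gy * (lc2 * c12))
    x <- l1 * c1 + l2 * c12; yy <- l1 * s1 + l2 * s12
    J11 <- -l1 * s1 - l2 * s12; J12 <- -l2 * s12
    J21 <- l1 * c1 + l2 * c12; J22 <- l2 * c12
    xd <- J11 * qd1 + J12 * qd2; yd <- J21 * qd1 + J22 * qd2
    phi <- om * t + ph0
    ex <- cx + r * cos(phi) - x
    ey <- cy + r * sin(phi) - yy
    Fx <- Kx11 * ex + Kx12 * ey - (Bx11 * xd + Bx12 * yd)
    Fy <- Kx12 * ex + Kx22 * ey - (Bx12 * xd + Bx22 * yd)
    e1 <- qr1 - q1; e2 <- qr2 - q2
    tau1 <- J11 * Fx + J21 * Fy + Kq11 * e1 + Kq12 * e2
    tau2 <- J12 * Fx + J22 * Fy + Kq12 * e1 + Kq22 * e2
    b1 <- tau1 - Cq1 - g1
    b2 <- tau2 - Cq2 - g2
    det <- M11 * M22 - M12 * M12
    list(c(qd1, qd2,
           (M22 * b1 - M12 * b2) / det,
           (-M12 * b1 + M11 * b2) / det))
  }
}

#' Work-energy audit of a steady cycle
#'
#' Checks the integrator against the mechanical power balance of the
#' controlled arm: over any interval,
#' `delta(KE + endpoint-spring + joint-spring + gravity PE)`
#' must equal `-int xdot' Bx xdot dt + int xrdot' Kx (xr - x) dt`
#' (the endpoint-spring energy is stored in the tracking-error frame, so the
#' moving reference injects power through it). Integrals are evaluated by
#' the trapezoidal rule on the output grid.
#'
#' @param traj An `arm_trajectory` from [simulate_steady_cycle()].
#' @return A tibble with one row: `delta_energy`, `work_damping`,
#'   `work_drive` (J), `residual` (J) and `residual_frac` (residual as a
#'   fraction of the dissipated energy).
#' @export
energy_audit <- function(traj) {
  params <- attr(traj, "params"); ctrl <- attr(traj, "ctrl")
  stopifnot(!is.null(params), !is.null(ctrl))
  n <- nrow(traj)
  ref <- reference_endpoint(ctrl, traj$t)
  ex <- ref$xr - traj$x; ey <- ref$yr - traj$y

  energy_at <- function(i) {
    q <- c(traj$q1[i], traj$q2[i]); qd <- c(traj$qd1[i], traj$qd2[i])
    dyn <- dynamics_terms(params, q, qd)
    ke <- 0.5 * sum(qd * (dyn$M %*% qd))
    e <- c(ex[i], ey[i])
    spring_x <- 0.5 * sum(e * (ctrl$Kx %*% e))
    dq <- ctrl$qr - q
    spring_q <- 0.5 * sum(dq * (ctrl$Kq %*% dq))
    gvec <- params$g_mag * params$g_dir
    pc1 <- params$lc1 * c(cos(q[1]), sin(q[1]))
    pc2 <- params$l1 * c(cos(q[1]), sin(q[1])) +
      params$lc2 * c(cos(q[1] + q[2]), sin(q[1] + q[2]))
    ug <- -params$m1 * sum(gvec * pc1) - params$m2 * sum(gvec * pc2)
    ke + spring_x + spring_q + ug
  }

  xdv <- cbind(traj$xd, traj$yd)
  p_damp <- rowSums((xdv %*% ctrl$Bx) * xdv)
  xrd <- cbind(ref$xrd, ref$yrd)
  kxe <- cbind(ex, ey) %*% ctrl$Kx
  p_drive <- rowSums(xrd * kxe)
  trapz <- function(y) sum(diff(traj$t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  work_damping <- trapz(p_damp)
  work_drive <- trapz(p_drive)
  delta_energy <- energy_at(n) - energy_at(1)
  residual <- delta_energy - (-work_damping + work_drive)
  tibble::tibble(
    delta_energy = delta_energy,
    work_damping = work_damping,
    work_drive = work_drive,
    residual = residual,
    residual_frac = abs(residual) / work_damping
  )
}
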