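#' Forward kinematics of the two-link arm
#'
#' Maps joint angles to elbow and endpoint (hand) positions. The shoulder is
#' fixed at the origin; `q1` is the shoulder angle from the +x axis and `q2`
#' the elbow angle relative to the first link.
#'
#' @param params An [arm_params()] object.
#' @param q Joint angles: a length-2 vector, or an n x 2 matrix / data frame
#'   with columns `q1`, `q2` for vectorized evaluation.
#' @return A tibble with one row per configuration and columns
#'   `x`, `y` (endpoint, m) and `elbow_x`, `elbow_y` (m).
#' @examples
#' forward_kinematics(arm_params(l1 = 0.3, l2 = 0.3), c(0, 0))
#' @export
forward_kinematics <- function(params, q) {
  q <- q_matrix(q)
  q1 <- q[, 1]; q12 <- q[, 1] + q[, 2]
  tibble::tibble(
    x = params$l1 * cos(q1) + params$l2 * cos(q12),
    y = params$l1 * sin(q1) + params$l2 * sin(q12),
    elbow_x = params$l1 * cos(q1),
    elbow_y = params$l1 * sin(q1)
  )
}

#' Endpoint Jacobian
#'
#' The 2x2 matrix of partial derivatives of endpoint position with respect
#' to the joint angles; its determinant is `l1 * l2 * sin(q2)`.
#'
#' @inheritParams forward_kinematics
#' @param q Length-2 vector of joint angles (rad).
#' @return A 2x2 numeric matrix (m/rad).
#' @export
arm_jacobian <- function(params, q) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-params$l1 * s1 - params$l2 * s12, -params$l2 * s12,
           params$l1 * c1 + params$l2 * c12,  params$l2 * c12),
         2, 2, byrow = TRUE)
}

#' Manipulator dynamics terms
#'
#' Inertia matrix `M(q)`, Coriolis/centrifugal matrix `C(q, qdot)` (built
#' from Christoffel symbols so `dM/dt - 2C` is skew-symmetric), and the
#' gravitational torque vector `g_tau(q)` (the configuration gradient of
#' gravitational potential energy) for the rigid two-link arm, which obeys
#' `M(q) qddot + C(q, qdot) qdot + g_tau(q) = tau`.
#'
#' @inheritParams arm_jacobian
#' @param qdot Length-2 vector of joint velocities (rad/s).
#' @return A list with elements `M` (2x2, kg m^2), `C` (2x2, kg m^2/s) and
#'   `g_tau` (length 2, N m).
#' @export
dynamics_terms <- function(params, q, qdot) {
  p <- params
  c2 <- cos(q[2]); s2 <- sin(q[2])
  a <- p$m2 * p$l1 * p$lc2
  M <- matrix(c(
    p$m1 * p$lc1^2 + p$I1 + p$m2 * (p$l1^2 + p$lc2^2 + 2 * p$l1 * p$lc2 * c2) + p$I2,
    p$m2 * p$lc2^2 + a * c2 + p$I2,
    p$m2 * p$lc2^2 + a * c2 + p$I2,
    p$m2 * p$lc2^2 + p$I2
  ), 2, 2)
  h <- a * s2
  C <- matrix(c(-h * qdot[2], h * qdot[1],
                -h * (qdot[1] + qdot[2]), 0), 2, 2)
  # g_tau = dU/dq with U = -sum_i m_i * gvec . p_ci
  gvec <- p$g_mag * p$g_dir
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  g1 <- -p$m1 * (gvec[1] * (-p$lc1 * s1) + gvec[2] * (p$lc1 * c1)) -
    p$m2 * (gvec[1] * (-p$l1 * s1 - p$lc2 * s12) +
              gvec[2] * (p$l1 * c1 + p$lc2 * c12))
  g2 <- -p$m2 * (gvec[1] * (-p$lc2 * s12) + gvec[2] * (p$lc2 * c12))
  list(M = M, C = C, g_tau = c(g1, g2))
}

#' Reference endpoint orbit
#'
#' Position and velocity of the circular endpoint reference at time `t`:
#' `xr = centre + radius * (cos(omega t + phase0), sin(omega t + phase0))`.
#'
#' @param ctrl A [controller_params()] object.
#' @param t Time (s), scalar or vector; must be `>= 0`.
#' @return A tibble with columns `t`, `xr`, `yr` (m) and `xrd`, `yrd` (m/s).
#' @export
reference_endpoint <- function(ctrl, t) {
  stopifnot(all(t >= 0))
  ph <- ctrl$omega * t + ctrl$phase0
  r <- ctrl$circle_radius
  tibble::tibble(
    t = t,
    xr = ctrl$circle_center[1] + r * cos(ph),
    yr = ctrl$circle_center[2] + r * sin(ph),
    xrd = -r * ctrl$omega * sin(ph),
    yrd = r * ctrl$omega * cos(ph)
  )
}

#' Controller joint torque
#'
#' The composed impedance-primitive control law
#' `tau = J(q)' Kx (xr - x) - J(q)' Bx xdot + Kq (qr - q)`,
#' with endpoint position `x` and velocity `xdot = J(q) qdot` obtained from
#' the forward kinematics.
#'
#' @inheritParams dynamics_terms
#' @param ctrl A [controller_params()] object.
#' @param t Time (s), used to evaluate the reference orbit.
#' @return Length-2 numeric vector of joint torques (N m).
#' @export
controller_torque <- function(ctrl, params, t, q, qdot) {
  fk <- forward_kinematics(params, q)
  J <- arm_jacobian(params, q)
  x <- c(fk$x, fk$y)
  xdot <- as.numeric(J %*% qdot)
  ref <- reference_endpoint(ctrl, t)
  xr <- c(ref$xr, ref$yr)
  as.numeric(t(J) %*% (ctrl$Kx %*% (xr - x)) - t(J) %*% (ctrl$Bx %*% xdot) +
               ctrl$Kq %*% (ctrl$qr - q))
}

#' Inverse kinematics (elbow-up branch)
#'
#' Joint angles whose endpoint is `target`, choosing the branch with
#' positive elbow angle `q2`. Used to seed the simulation on the reference
#' orbit.
#'
#' @inheritParams forward_kinematics
#' @param target Length-2 endpoint position (m), inside the reachable
#'   annulus `[|l1 - l2|, l1 + l2]`.
#' @return Length-2 vector `c(q1, q2)` (rad).
#' @export
inverse_kinematics <- function(params, target) {
  d2 <- sum(target^2)
  c2 <- (d2 - params$l1^2 - params$l2^2) / (2 * params$l1 * params$l2)
  if (c2 > 1 + 1e-9 || c2 < -1 - 1e-9) {
    stop("target endpoint is outside the reachable workspace")
  }
  q2 <- acos(min(1, max(-1, c2)))  # positive (elbow-up) branch
  q1 <- atan2(target[2], target[1]) -
    atan2(params$l2 * sin(q2), params$l1 + params$l2 * cos(q2))
  c(q1, q2)
}

# coerce joint-angle input to an n x 2 matrix
q_matrix <- function(q) {
  if (is.data.frame(q)) q <- as.matrix(q[, c("q1", "q2")])
  if (is.null(dim(q))) {
    stopifnot(length(q) == 2)
    q <- matrix(q, 1, 2)
  }
  stopifnot(ncol(q) == 2)
  q
}
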