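#' Anthropometric parameters of the two-link planar arm
#'
#' Bundles link geometry, inertia and gravity for the simulated arm. The
#' defaults describe the upper arm (proximal link) and forearm-plus-hand
#' (distal link) of an average adult male from standard body-segment tables;
#' every field is configurable.
#'
#' @param l1,l2 Link lengths (m).
#' @param m1,m2 Link masses (kg).
#' @param lc1,lc2 Distance from each proximal joint to the link's centre of
#'   mass (m); must satisfy `0 < lc_i <= l_i`.
#' @param I1,I2 Moments of inertia about each link's centre of mass (kg m^2).
#' @param g_mag Gravitational acceleration magnitude (m/s^2). Set to 0 to
#'   simulate a gravity-free (horizontal) plane.
#' @param g_dir Unit 2-vector giving the direction of gravity in the plane of
#'   motion. The default `c(0, -1)` is a vertical plane with gravity along -y.
#'
#' @return An object of class `arm_params` (a named list).
#' @examples
#' p <- arm_params()
#' forward_kinematics(p, c(pi / 4, pi / 4))
#' @export
arm_params <- function(l1 = 0.33, l2 = 0.32,
                       m1 = 2.10, m2 = 1.65,
                       lc1 = 0.144, lc2 = 0.218,
                       I1 = 0.024, I2 = 0.037,
                       g_mag = 9.81, g_dir = c(0, -1)) {
  stopifnot(
    l1 > 0, l2 > 0, m1 > 0, m2 > 0, I1 > 0, I2 > 0,
    lc1 > 0, lc1 <= l1, lc2 > 0, lc2 <= l2,
    g_mag >= 0, length(g_dir) == 2
  )
  nrm <- sqrt(sum(g_dir^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm == 0) stop("`g_dir` must be a nonzero direction vector")
    g_dir <- g_dir / nrm
  }
  structure(
    list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, lc1 = lc1, lc2 = lc2,
         I1 = I1, I2 = I2, g_mag = g_mag, g_dir = g_dir),
    class = "arm_params"
  )
}

#' Impedance-controller parameters
#'
#' The controller superimposes two primitives: an oscillatory attractor with
#' mechanical impedance in endpoint coordinates (stiffness `Kx`, damping
#' `Bx`, circular reference orbit `xr(t)`), and a fixed-point attractor with
#' impedance in joint coordinates (stiffness `Kq` toward the reference
#' configuration `qr`). In the default configuration `Kq` is zero except for
#' its elbow diagonal entry `E`, the single parameter varied across stimuli.
#'
#' @param Kx 2x2 symmetric endpoint stiffness matrix (N/m).
#' @param Bx 2x2 symmetric endpoint damping matrix (N s/m).
#' @param E Elbow joint stiffness (N m/rad), the `[2, 2]` entry of `Kq`.
#' @param Kq Optional full 2x2 joint stiffness matrix; overrides `E` if
#'   given (its `[2, 2]` entry is then reported as `E`).
#' @param qr Reference joint configuration (rad).
#' @param circle_center Centre of the circular endpoint reference orbit (m).
#'   The default places the orbit inside the arm's workspace at a distance
#'   from the shoulder calibrated so that constant-speed traversal times of
#'   the steady paths span roughly 3.33 s (E = 0) to 3.68 s (E = 50).
#' @param circle_radius Radius of the reference orbit (m).
#' @param period Period of the reference orbit (s); `omega = 2*pi/period`.
#' @param phase0 Phase of the reference at `t = 0` (rad).
#'
#' @return An object of class `controller_params` (a named list with
#'   elements `Kx`, `Bx`, `Kq`, `E`, `qr`, `circle_center`, `circle_radius`,
#'   `omega`, `period`, `phase0`).
#' @examples
#' ctrl <- controller_params(E = 30)
#' reference_endpoint(ctrl, c(0, ctrl$period / 4))
#' @export
controller_params <- function(Kx = diag(c(500, 500)),
                              Bx = diag(c(10, 10)),
                              E = 0,
                              Kq = NULL,
                              qr = c(pi / 4, pi / 4),
                              circle_center = c(0.255, 0.255),
                              circle_radius = 0.1,
                              period = 3.33,
                              phase0 = 0) {
  if (is.null(Kq)) {
    stopifnot(is.numeric(E), length(E) == 1, E >= 0)
    Kq <- matrix(c(0, 0, 0, E), 2, 2)
  } else {
    Kq <- as.matrix(Kq)
    E <- Kq[2, 2]
  }
  Kx <- as.matrix(Kx); Bx <- as.matrix(Bx)
  for (nm in c("Kx", "Bx", "Kq")) {
    m <- get(nm)
    if (!all(dim(m) == c(2, 2)) || max(abs(m - t(m))) > 1e-10) {
      stop("`", nm, "` must be a symmetric 2x2 matrix")
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("`", nm, "` must have nonnegative eigenvalues")
    }
  }
  stopifnot(
    length(qr) == 2, length(circle_center) == 2,
    circle_radius > 0, period > 0
  )
  structure(
    list(Kx = Kx, Bx = Bx, Kq = Kq, E = E, qr = qr,
         circle_center = circle_center, circle_radius = circle_radius,
         omega = 2 * pi / period, period = period, phase0 = phase0),
    class = "controller_params"
  )
}

#' @export
print.arm_params <- function(x, ...) {
  cat("<arm_params>\n")
  cat(sprintf("  links   l = (%.3f, %.3f) m, m = (%.2f, %.2f) kg\n",
              x$l1, x$l2, x$m1, x$m2))
  cat(sprintf("  com     lc = (%.3f, %.3f) m, I = (%.3f, %.3f) kg m^2\n",
              x$lc1, x$lc2, x$I1, x$I2))
  cat(sprintf("  gravity %.2f m/s^2 along (%.2f, %.2f)\n",
              x$g_mag, x$g_dir[1], x$g_dir[2]))
  invisible(x)
}

#' @export
print.controller_params <- function(x, ...) {
  cat("<controller_params>\n")
  cat(sprintf("  Kx = diag(%.0f, %.0f) N/m, Bx = diag(%.0f, %.0f) N s/m, E = %g N m/rad\n",
              x$Kx[1, 1], x$Kx[2, 2], x$Bx[1, 1], x$Bx[2, 2], x$E))
  cat(sprintf("  reference circle: centre (%.3f, %.3f) m, radius %.3f m, period %.3f s\n",
              x$circle_center[1], x$circle_center[2], x$circle_radius, x$period))
  cat(sprintf("  qr = (%.3f, %.3f) rad\n", x$qr[1], x$qr[2]))
  invisible(x)
}
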