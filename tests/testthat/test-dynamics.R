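test_that("forward kinematics matches hand-evaluated configurations", {
  p <- arm_params(l1 = 0.3, l2 = 0.3)
  fk <- forward_kinematics(p, c(0, 0))
  expect_equal(c(fk$x, fk$y), c(0.6, 0), tolerance = 1e-12)
  fk <- forward_kinematics(p, c(pi / 2, pi / 2))
  expect_equal(c(fk$x, fk$y), c(-0.3, 0.3), tolerance = 1e-12)

  fk <- forward_kinematics(arm_params(), c(pi / 4, pi / 4))
  expect_equal(c(fk$x, fk$y),
               c(0.33 * cos(pi / 4), 0.33 * sin(pi / 4) + 0.32),
               tolerance = 1e-12)
  expect_equal(round(c(fk$x, fk$y), 4), c(0.2333, 0.5533))
})

test_that("forward kinematics is vectorized and inverse kinematics inverts it", {
  p <- arm_params()
  set.seed(11)
  q <- cbind(runif(20, -pi, pi), runif(20, 0.1, pi - 0.1))
  fk <- forward_kinematics(p, q)
  expect_equal(nrow(fk), 20)
  for (i in c(1, 7, 20)) {
    qi <- inverse_kinematics(p, c(fk$x[i], fk$y[i]))
    fki <- forward_kinematics(p, qi)
    expect_equal(c(fki$x, fki$y), c(fk$x[i], fk$y[i]), tolerance = 1e-10)
    expect_gt(qi[2], 0) # elbow-up branch
  }
  expect_error(inverse_kinematics(p, c(2, 2)), "workspace")
})

test_that("Jacobian matches closed forms and a finite-difference oracle", {
  p <- arm_params(l1 = 0.3, l2 = 0.3)
  expect_equal(arm_jacobian(p, c(0, 0)),
               matrix(c(0, 0, 0.6, 0.3), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(det(arm_jacobian(p, c(0.4, pi / 2))), 0.09, tolerance = 1e-12)

  pd <- arm_params()
  set.seed(21)
  for (i in 1:20) {
    q <- c(runif(1, -pi, pi), runif(1, -pi, pi))
    expect_equal(det(arm_jacobian(pd, q)), pd$l1 * pd$l2 * sin(q[2]),
                 tolerance = 1e-12)
    eps <- 1e-6
    Jfd <- matrix(0, 2, 2)
    for (j in 1:2) {
      dq <- c(0, 0); dq[j] <- eps
      fp <- forward_kinematics(pd, q + dq)
      fm <- forward_kinematics(pd, q - dq)
      Jfd[, j] <- c(fp$x - fm$x, fp$y - fm$y) / (2 * eps)
    }
    expect_equal(arm_jacobian(pd, q), Jfd, tolerance = 1e-6)
  }
})

test_that("dynamics terms have the standard two-link structure", {
  p <- arm_params()
  d <- dynamics_terms(p, c(0.3, 0.8), c(0, 0))
  expect_equal(as.numeric(d$C %*% c(0, 0)), c(0, 0))
  expect_equal(d$M, t(d$M))

  # closed-form off-diagonal inertia when the cosine term vanishes
  d <- dynamics_terms(p, c(0.2, pi / 2), c(0.1, -0.2))
  expect_equal(d$M[1, 2], p$I2 + p$m2 * p$lc2^2, tolerance = 1e-12)

  # gravity off: no gravitational torque
  p0 <- arm_params(g_mag = 0)
  expect_equal(dynamics_terms(p0, c(0.4, 0.9), c(0, 0))$g_tau, c(0, 0))

  # gravitational torque equals the finite-difference potential gradient
  U <- function(q) {
    gvec <- p$g_mag * p$g_dir
    pc1 <- p$lc1 * c(cos(q[1]), sin(q[1]))
    pc2 <- p$l1 * c(cos(q[1]), sin(q[1])) +
      p$lc2 * c(cos(q[1] + q[2]), sin(q[1] + q[2]))
    -p$m1 * sum(gvec * pc1) - p$m2 * sum(gvec * pc2)
  }
  set.seed(5)
  for (i in 1:5) {
    q <- runif(2, -pi, pi)
    eps <- 1e-6
    gfd <- sapply(1:2, function(j) {
      dq <- c(0, 0); dq[j] <- eps
      (U(q + dq) - U(q - dq)) / (2 * eps)
    })
    expect_equal(dynamics_terms(p, q, c(0, 0))$g_tau, gfd, tolerance = 1e-6)
  }
})

test_that("M is SPD and dM/dt - 2C is skew-symmetric at random states", {
  p <- arm_params()
  set.seed(31)
  for (i in 1:100) {
    q <- runif(2, -pi, pi)
    qd <- runif(2, -5, 5)
    d <- dynamics_terms(p, q, qd)
    ev <- eigen(d$M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    eps <- 1e-6
    Mdot <- (dynamics_terms(p, q + eps * qd, qd)$M -
               dynamics_terms(p, q - eps * qd, qd)$M) / (2 * eps)
    S <- Mdot - 2 * d$C
    expect_lt(max(abs(S + t(S))), 1e-8)
  }
})

test_that("reference orbit has the printed radius and speed", {
  ctrl <- controller_params()
  r0 <- reference_endpoint(ctrl, 0)
  expect_equal(c(r0$xr, r0$yr), ctrl$circle_center + c(0.1, 0),
               tolerance = 1e-12)
  rq <- reference_endpoint(ctrl, ctrl$period / 4)
  expect_equal(c(rq$xr, rq$yr), ctrl$circle_center + c(0, 0.1),
               tolerance = 1e-12)
  tt <- seq(0, 5, by = 0.37)
  ref <- reference_endpoint(ctrl, tt)
  expect_equal(sqrt(ref$xrd^2 + ref$yrd^2),
               rep(0.1 * 2 * pi / 3.33, length(tt)), tolerance = 1e-12)
  expect_equal(0.1 * 2 * pi / 3.33, 0.1886, tolerance = 1e-3)
  expect_error(reference_endpoint(ctrl, -1))
})

test_that("controller torque vanishes at the reference and matches brute force", {
  p <- arm_params()
  ctrl <- controller_params(E = 30)
  # configuration on the reference with zero velocity and q = qr:
  # place the reference at the qr endpoint so x = xr exactly
  fkr <- forward_kinematics(p, ctrl$qr)
  ctrl0 <- controller_params(E = 30, circle_center = c(fkr$x - 0.1, fkr$y),
                             qr = ctrl$qr)
  tau <- controller_torque(ctrl0, p, 0, ctrl$qr, c(0, 0))
  expect_equal(tau, c(0, 0), tolerance = 1e-10)

  # with E = 0 the joint term contributes nothing even when q != qr
  q_off <- inverse_kinematics(p, c(fkr$x, fkr$y))
  ctrlE0 <- controller_params(E = 0, circle_center = c(fkr$x - 0.1, fkr$y))
  expect_equal(controller_torque(ctrlE0, p, 0, q_off, c(0, 0)), c(0, 0),
               tolerance = 1e-10)

  # brute-force term-by-term evaluation at random states
  set.seed(41)
  for (i in 1:10) {
    q <- runif(2, -1, 2); qd <- runif(2, -3, 3); t <- runif(1, 0, 10)
    l1 <- p$l1; l2 <- p$l2
    J <- rbind(c(-l1 * sin(q[1]) - l2 * sin(sum(q)), -l2 * sin(sum(q))),
               c(l1 * cos(q[1]) + l2 * cos(sum(q)), l2 * cos(sum(q))))
    x <- c(l1 * cos(q[1]) + l2 * cos(sum(q)),
           l1 * sin(q[1]) + l2 * sin(sum(q)))
    xr <- ctrl$circle_center +
      0.1 * c(cos(2 * pi * t / 3.33), sin(2 * pi * t / 3.33))
    expected <- t(J) %*% (diag(c(500, 500)) %*% (xr - x)) -
      t(J) %*% (diag(c(10, 10)) %*% (J %*% qd)) +
      matrix(c(0, 0, 0, 30), 2, 2) %*% (c(pi / 4, pi / 4) - q)
    expect_equal(controller_torque(ctrl, p, t, q, qd), as.numeric(expected),
                 tolerance = 1e-10)
  }
})

test_that("the integrator RHS agrees with the modular dynamics assembly", {
  p <- arm_params()
  ctrl <- controller_params(E = 20)
  rhs <- stiffsim:::make_arm_rhs(p, ctrl)
  set.seed(51)
  for (i in 1:10) {
    q <- runif(2, -1, 2); qd <- runif(2, -3, 3); t <- runif(1, 0, 10)
    d <- dynamics_terms(p, q, qd)
    tau <- controller_torque(ctrl, p, t, q, qd)
    qdd <- solve(d$M, tau - d$C %*% qd - d$g_tau)
    got <- rhs(t, c(q, qd), NULL)[[1]]
    expect_equal(got, c(qd, as.numeric(qdd)), tolerance = 1e-10)
  }
})
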