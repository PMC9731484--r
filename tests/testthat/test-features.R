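test_that("circle path summary matches analytic values", {
  circ <- make_circle(r = 0.1, n = 1000, center = c(0.3, 0.2))
  ps <- path_summary(circ)
  expect_equal(ps$oblongness, 1, tolerance = 0.01)
  expect_equal(ps$area, pi * 0.1^2, tolerance = 0.01)
  expect_equal(ps$mean_curvature, 10, tolerance = 0.01)
  expect_equal(c(ps$centroid_x, ps$centroid_y), c(0.3, 0.2), tolerance = 1e-6)
})

test_that("ellipse oblongness is the covariance eigenvalue ratio a^2/b^2", {
  ell <- make_ellipse(a = 0.2, b = 0.1, n = 1000)
  # uniform angular samples, equal-weight covariance: eigenvalues a^2/2, b^2/2
  ps <- path_summary(ell, weighted = FALSE)
  expect_equal(ps$oblongness, 4, tolerance = 0.01)
  expect_equal(ps$area, pi * 0.2 * 0.1, tolerance = 0.01)
})

test_that("degenerate zero-variance paths fail oblongness", {
  seg <- tibble::tibble(x = c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1]),
                        y = rep(0, 51))
  expect_error(path_summary(seg), "degenerate")
})

test_that("joint summary recovers ROM and relative phase of sinusoids", {
  om <- 2 * pi; n <- 800
  t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  traj <- tibble::tibble(
    t = t,
    q1 = pi / 4 + 0.2 * sin(om * t),
    q2 = pi / 4 + 0.3 * sin(om * t - pi / 2),
    x = cos(2 * pi * t), y = sin(2 * pi * t)
  )
  js <- joint_summary(traj)
  expect_equal(js$shoulder_rom, 0.4, tolerance = 1e-3)
  expect_equal(js$elbow_rom, 0.6, tolerance = 1e-3)
  expect_equal(js$relative_phase, pi / 2, tolerance = 0.02)

  traj$q2 <- traj$q1
  expect_equal(joint_summary(traj)$relative_phase, 0)

  # leading elbow gives a negative phase
  traj$q2 <- pi / 4 + 0.3 * sin(om * t + pi / 2)
  expect_equal(joint_summary(traj)$relative_phase, -pi / 2, tolerance = 0.02)

  traj$q2 <- rep(pi / 4, n)
  expect_true(is.na(joint_summary(traj)$relative_phase))
})

test_that("relative phase survives 5% measurement noise", {
  om <- 2 * pi; n <- 800
  t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  set.seed(61)
  traj <- tibble::tibble(
    t = t,
    q1 = 0.2 * sin(om * t) + rnorm(n, 0, 0.01),
    q2 = 0.3 * sin(om * t - 1.1) + rnorm(n, 0, 0.015),
    x = cos(2 * pi * t), y = sin(2 * pi * t)
  )
  expect_equal(joint_summary(traj)$relative_phase, 1.1, tolerance = 0.05)
})

test_that("RMS derivatives of sinusoidal motion match A omega^k / sqrt(2)", {
  om <- 1.886; A <- 0.1
  n <- 2000
  period <- 2 * pi / om
  t <- seq(0, period, length.out = n + 1)[-(n + 1)]
  traj <- tibble::tibble(
    t = t,
    q1 = pi / 4 + A * sin(om * t), q2 = pi / 3 + 0.05 * cos(om * t),
    x = 0.3 + 0.1 * cos(om * t), y = 0.3 + 0.1 * sin(om * t)
  )
  r <- rms_kinematics(traj)
  expect_equal(r$rms_vel_shoulder, A * om / sqrt(2), tolerance = 0.01)
  expect_equal(r$rms_acc_shoulder, A * om^2 / sqrt(2), tolerance = 0.01)
  expect_equal(r$rms_jerk_shoulder, A * om^3 / sqrt(2), tolerance = 0.01)
  # endpoint speed on the circular path is constant r*omega
  expect_equal(r$rms_vel_end, 0.1 * om, tolerance = 0.01)

  # refinement: halving the sample spacing barely moves any RMS value
  t2 <- seq(0, period, length.out = 2 * n + 1)[-(2 * n + 1)]
  traj2 <- tibble::tibble(
    t = t2,
    q1 = pi / 4 + A * sin(om * t2), q2 = pi / 3 + 0.05 * cos(om * t2),
    x = 0.3 + 0.1 * cos(om * t2), y = 0.3 + 0.1 * sin(om * t2)
  )
  r2 <- rms_kinematics(traj2)
  for (cl in names(r)) {
    expect_lt(abs(r2[[cl]] - r[[cl]]) / r[[cl]], 0.005)
  }
})

test_that("constant-condition stimuli have RMS endpoint speed 0.185 m/s", {
  rc <- retime_constant(get_sim(0), 0.185)
  expect_equal(rms_kinematics(rc)$rms_vel_end, 0.185, tolerance = 0.005)
})

test_that("path features are invariant across timing conditions; RMS features are not", {
  stim <- build_stimulus_set(2, sims = get_sims_list())
  feats <- extract_features(stim)
  path_cols <- c("centroid_x", "centroid_y", "oblongness", "area",
                 "mean_curvature", "shoulder_rom", "elbow_rom",
                 "relative_phase")
  for (cl in path_cols) {
    expect_equal(length(unique(feats[[cl]])), 1)
  }
  rms_cols <- grep("^rms_", names(feats), value = TRUE)
  differing <- vapply(rms_cols, function(cl) length(unique(feats[[cl]])) > 1,
                      logical(1))
  expect_true(any(differing))
})

test_that("centroid spacing shrinks and elbow ROM falls as E grows", {
  feats <- extract_features(build_stimulus_set(
    1, conditions = "original", sims = get_sims_list()
  ))
  feats <- feats[order(feats$E), ]
  cen <- cbind(feats$centroid_x, feats$centroid_y)
  spacing <- sqrt(rowSums(diff(cen)^2))
  expect_true(all(diff(spacing) < 0)) # strictly decreasing, Fig-2-like
  expect_true(all(diff(feats$elbow_rom) < 0))
})
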