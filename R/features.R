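#' Geometric summary of an endpoint path
#'
#' Path-only descriptors of one closed endpoint cycle: centroid, oblongness
#' (ratio of the larger to smaller eigenvalue of the position covariance; 1
#' for a circle), enclosed area (shoelace formula), and mean curvature (the
#' average reciprocal radius of curvature). By default the centroid,
#' covariance and mean curvature are arc-length weighted so the values do
#' not depend on how the path is sampled in time.
#'
#' @param traj A trajectory tibble with columns `x`, `y`.
#' @param geom Optional precomputed [path_geometry()] of `traj`.
#' @param weighted Arc-length weighting of centroid, covariance and mean
#'   curvature (default). `FALSE` gives every sample equal weight.
#' @return A one-row tibble: `centroid_x`, `centroid_y` (m), `oblongness`
#'   (>= 1), `area` (m^2), `mean_curvature` (1/m).
#' @export
path_summary <- function(traj, geom = NULL, weighted = TRUE) {
  if (is.null(geom)) geom <- path_geometry(traj)
  xy <- cbind(traj$x, traj$y)
  n <- nrow(xy)
  dup <- has_closing_duplicate(xy)
  m <- if (dup) n - 1L else n
  P <- xy[seq_len(m), , drop = FALSE]
  Rinv <- 1 / geom$R[seq_len(m)]

  chords <- sqrt(rowSums((P[c(seq(2, m), 1), , drop = FALSE] - P)^2))
  w <- if (weighted) (chords + chords[c(m, seq_len(m - 1))]) / 2 else rep(1, m)
  w <- w / sum(w)

  centroid <- colSums(P * w)
  D <- sweep(P, 2, centroid)
  covw <- crossprod(D * w, D)  # sum_i w_i d_i d_i'
  ev <- eigen(covw, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-12) {
    stop("degenerate (zero-variance) path; oblongness undefined")
  }
  area <- abs(sum(P[, 1] * P[c(seq(2, m), 1), 2] -
                    P[c(seq(2, m), 1), 1] * P[, 2])) / 2
  tibble::tibble(
    centroid_x = centroid[1], centroid_y = centroid[2],
    oblongness = ev[1] / ev[2],
    area = area,
    mean_curvature = sum(Rinv * w)
  )
}

#' Joint-space summary of one cycle
#'
#' Shoulder and elbow ranges of motion (max minus min joint angle) and the
#' relative phase between the two joint oscillations. Relative phase is the
#' lag of the peak of the circular cross-correlation of the mean-removed
#' joint angles, expressed as an angle in `(-pi, pi]`; it is positive when
#' the elbow lags the shoulder. The lag is found in samples, so the value
#' is a pure path/joint feature, invariant under retiming.
#'
#' @param traj A trajectory tibble with columns `q1`, `q2`.
#' @return A one-row tibble: `shoulder_rom`, `elbow_rom` (rad),
#'   `relative_phase` (rad, `NA` if either joint signal is constant).
#' @export
joint_summary <- function(traj) {
  q1 <- traj$q1; q2 <- traj$q2
  n <- length(q1)
  if (has_closing_duplicate(cbind(traj$x, traj$y))) {
    q1 <- q1[-n]; q2 <- q2[-n]
  }
  tibble::tibble(
    shoulder_rom = max(traj$q1) - min(traj$q1),
    elbow_rom = max(traj$q2) - min(traj$q2),
    relative_phase = circular_phase(q1, q2)
  )
}

# lag (in samples) of the peak of the circular cross-correlation
# r[k] = sum_i a[i] * b[i + k], converted to an angle in (-pi, pi];
# positive when b is a delayed copy of a.
circular_phase <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  m <- length(a)
  r <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / m
  k <- which.max(r) - 1L
  phase <- 2 * pi * k / m
  if (phase > pi) phase <- phase - 2 * pi
  phase
}

#' RMS velocity, acceleration and jerk over one cycle
#'
#' Time-weighted root-mean-square first, second and third derivatives of
#' the motion with respect to the stimulus time vector (`t_new` if present,
#' else `t`), in joint coordinates (per joint, rad/s^k) and endpoint
#' coordinates (magnitude of the Cartesian derivative vector, m/s^k).
#' Derivatives are taken by second-order central finite differences on the
#' possibly nonuniform grid, applied successively, with periodic wrap over
#' the cycle.
#'
#' @param traj A trajectory tibble with columns `q1`, `q2`, `x`, `y` and a
#'   strictly increasing time vector.
#' @return A one-row tibble with columns `rms_vel_shoulder`,
#'   `rms_vel_elbow`, `rms_acc_shoulder`, `rms_acc_elbow`,
#'   `rms_jerk_shoulder`, `rms_jerk_elbow` (rad/s, rad/s^2, rad/s^3) and
#'   `rms_vel_end`, `rms_acc_end`, `rms_jerk_end` (m/s, m/s^2, m/s^3).
#' @export
rms_kinematics <- function(traj) {
  tt <- time_column(traj)
  n <- nrow(traj)
  cols <- cbind(traj$q1, traj$q2, traj$x, traj$y)
  if (has_closing_duplicate(cbind(traj$x, traj$y))) {
    period <- tt[n] - tt[1]
    cols <- cols[-n, , drop = FALSE]
    tt <- tt[-n]
  } else {
    period <- (tt[n] - tt[1]) * n / (n - 1)
  }
  if (any(diff(tt) <= 0)) stop("time vector must be strictly increasing")
  d <- function(mat) apply(mat, 2, fd1_periodic, tt = tt, period = period)
  vel <- d(cols); acc <- d(vel); jerk <- d(acc)
  w <- periodic_weights(tt, period)
  rms <- function(v) sqrt(sum(w * v^2) / period)
  rms_mag <- function(mat) sqrt(sum(w * (mat[, 1]^2 + mat[, 2]^2)) / period)
  tibble::tibble(
    rms_vel_shoulder = rms(vel[, 1]), rms_vel_elbow = rms(vel[, 2]),
    rms_acc_shoulder = rms(acc[, 1]), rms_acc_elbow = rms(acc[, 2]),
    rms_jerk_shoulder = rms(jerk[, 1]), rms_jerk_elbow = rms(jerk[, 2]),
    rms_vel_end = rms_mag(vel[, 3:4]),
    rms_acc_end = rms_mag(acc[, 3:4]),
    rms_jerk_end = rms_mag(jerk[, 3:4])
  )
}

#' Feature table of a stimulus set
#'
#' Runs [path_summary()], [joint_summary()] and [rms_kinematics()] on every
#' stimulus of a [build_stimulus_set()] result and returns one row per
#' stimulus. Path and joint-geometry features are identical across the four
#' timing conditions of a given path; the RMS temporal features are not.
#'
#' @param stimuli A stimulus tibble from [build_stimulus_set()].
#' @return A tibble with columns `experiment`, `E`, `condition`, `duration`,
#'   `loops` and all feature columns.
#' @export
extract_features <- function(stimuli) {
  feats <- purrr::map(stimuli$trajectory, function(traj) {
    geom <- path_geometry(traj)
    dplyr::bind_cols(
      path_summary(traj, geom = geom),
      joint_summary(traj),
      rms_kinematics(traj)
    )
  })
  dplyr::bind_cols(
    stimuli[, c("experiment", "E", "condition", "duration", "loops")],
    dplyr::bind_rows(feats)
  )
}
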