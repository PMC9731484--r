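#' Velocity-profile manipulations of a sampled path
#'
#' Each `retime_*()` function returns a copy of the trajectory with a new
#' strictly increasing time vector `t_new` and a `condition` column;
#' position samples are never altered, so all path geometry is preserved
#' bit-for-bit and only the temporal pattern along the path changes.
#'
#' * `retime_original()` keeps the dynamics' own timing (`t_new = t - t[1]`).
#' * `retime_constant()` enforces a constant tangential speed `v`:
#'   `t_new[i] = s[i] / v`, giving total duration `total_length / v`.
#' * `retime_inverse()` enforces the inverse speed-curvature power law
#'   `v(t) = K * R(t)^(-1/3)` (speed highest where the path bends most),
#'   with the gain `K` tuned so the total duration matches
#'   `target_duration` (by default, the same path's constant-condition
#'   duration, mirroring the per-path period matching of the stimuli).
#' * `retime_variable()` transplants another stimulus' time vector verbatim,
#'   by ordinal sample index; all trajectories simulated on the shared
#'   output grid have equal sample counts, so the transplant is well posed.
#'
#' @param traj An `arm_trajectory` (or any tibble with columns `t`, `x`,
#'   `y`).
#' @param v Constant tangential speed (m/s).
#' @param geom Optional precomputed [path_geometry()] of `traj`.
#' @param target_duration Total traversal duration to match (s); default is
#'   the constant-condition duration `total_length / v`.
#' @param donor A retimed trajectory whose `t_new` is transplanted.
#' @return The input tibble plus columns `t_new` (s) and `condition`, with
#'   attributes describing the manipulation (`v_target`, `K_gain`,
#'   `source_E`, `duration`).
#' @name retime
NULL

#' @rdname retime
#' @export
retime_original <- function(traj) {
  finish_retime(traj, traj$t - traj$t[1], "original")
}

#' @rdname retime
#' @export
retime_constant <- function(traj, v = 0.185, geom = NULL) {
  stopifnot(v > 0)
  if (is.null(geom)) geom <- path_geometry(traj)
  out <- finish_retime(traj, geom$s / v, "constant")
  attr(out, "v_target") <- v
  out
}

#' @rdname retime
#' @export
retime_inverse <- function(traj, target_duration = NULL, v = 0.185,
                           geom = NULL) {
  if (is.null(geom)) geom <- path_geometry(traj)
  if (is.null(target_duration)) {
    target_duration <- attr(geom, "total_length") / v
  }
  stopifnot(target_duration > 0)
  # dt = ds / v = ds * R^(1/3) / K; duration is exactly S / K with
  # S = integral of R^(1/3) ds, so the gain solves the matching directly.
  r3 <- geom$R^(1 / 3)
  if (!all(is.finite(r3)) || all(diff(geom$s) == 0)) {
    stop("degenerate radius-of-curvature profile; cannot tune the gain")
  }
  ds <- diff(geom$s)
  seg <- ds * (utils::head(r3, -1) + utils::tail(r3, -1)) / 2
  S <- sum(seg)
  K <- S / target_duration
  t_new <- c(0, cumsum(seg / K))
  out <- finish_retime(traj, t_new, "inverse")
  attr(out, "K_gain") <- K
  out
}

#' @rdname retime
#' @export
retime_variable <- function(traj, donor) {
  stopifnot("t_new" %in% names(donor))
  if (nrow(donor) != nrow(traj)) {
    stop("donor and target trajectories must have equal sample counts (",
         nrow(donor), " vs ", nrow(traj), ")")
  }
  out <- finish_retime(traj, donor$t_new, "variable")
  attr(out, "source_E") <- attr(donor, "E")
  out
}

finish_retime <- function(traj, t_new, condition) {
  if (any(diff(t_new) <= 0)) {
    stop("retiming produced a non-increasing time vector")
  }
  out <- traj
  out$t_new <- t_new
  out$condition <- condition
  for (a in c("params", "ctrl", "E", "period", "meta")) {
    attr(out, a) <- attr(traj, a)
  }
  attr(out, "condition") <- condition
  attr(out, "duration") <- t_new[length(t_new)] - t_new[1]
  class(out) <- unique(c("arm_trajectory", class(tibble::tibble())))
  out
}

#' Numerically estimated tangential speed
#'
#' Per-sample endpoint speed of a (possibly retimed) trajectory, from
#' periodic central finite differences of position with respect to the
#' trajectory's time vector (`t_new` if present, else `t`). Used to verify
#' the retiming contracts.
#'
#' @param traj A trajectory tibble with columns `x`, `y` and `t`/`t_new`.
#' @return Numeric vector of speeds (m/s), one per unique sample (the
#'   closing duplicate of a closed cycle, if present, is dropped). Cycles
#'   stored with their closing sample are differenced with periodic wrap;
#'   otherwise interior samples use central differences and the two edge
#'   samples one-sided ones.
#' @export
tangential_speed <- function(traj) {
  tt <- time_column(traj)
  xy <- cbind(traj$x, traj$y)
  m <- nrow(xy)
  if (has_closing_duplicate(xy)) {
    period <- tt[m] - tt[1]
    keep <- seq_len(m - 1L)
    xy <- xy[keep, , drop = FALSE]
    tt <- tt[keep]
    vx <- fd1_periodic(xy[, 1], tt, period)
    vy <- fd1_periodic(xy[, 2], tt, period)
  } else {
    vx <- fd1_open(xy[, 1], tt)
    vy <- fd1_open(xy[, 2], tt)
  }
  sqrt(vx^2 + vy^2)
}

#' Assemble the stimulus set of an experiment
#'
#' Builds the full cross of endpoint paths and velocity-profile conditions.
#' Experiment 1 crosses the simulated elbow-stiffness paths
#' (`E_values`, default 0-50 N m/rad) with the four conditions, giving 24
#' stimuli. Experiment 2 uses the single `path_E` path (default
#' 30 N m/rad) under the four conditions; its four stimuli share the
#' endpoint path sample-for-sample. The `variable` condition transplants
#' the time vector of the `donor_E` (default 50 N m/rad) constant-condition
#' stimulus. Each stimulus is annotated with the number of loops needed to
#' fill `display_duration` seconds of display.
#'
#' @param experiment 1 or 2.
#' @param params,ctrl Arm and controller parameter objects; `ctrl$E` is
#'   overridden per stimulus.
#' @param E_values Elbow stiffness values for Experiment 1 (N m/rad).
#' @param conditions Subset of
#'   `c("original", "constant", "inverse", "variable")`.
#' @param v_constant Constant-condition tangential speed (m/s).
#' @param path_E Elbow stiffness of the Experiment 2 path (N m/rad).
#' @param donor_E Elbow stiffness whose constant-condition time vector the
#'   variable condition transplants (N m/rad).
#' @param display_duration Display time each stimulus must fill (s).
#' @param sims Optional named list of precomputed steady cycles (names are
#'   E values, as by `as.character(E)`); missing entries are simulated.
#' @param ... Passed on to [simulate_steady_cycle()].
#' @return A nested tibble with one row per stimulus: `experiment`, `E`,
#'   `condition`, `duration` (s), `loops`, and a `trajectory` list-column
#'   of retimed trajectories.
#' @export
build_stimulus_set <- function(experiment = 1,
                               params = arm_params(),
                               ctrl = controller_params(),
                               E_values = c(0, 10, 20, 30, 40, 50),
                               conditions = c("original", "constant",
                                              "inverse", "variable"),
                               v_constant = 0.185,
                               path_E = 30,
                               donor_E = 50,
                               display_duration = 20,
                               sims = NULL, ...) {
  stopifnot(experiment %in% c(1, 2))
  if (length(E_values) == 0 || any(E_values < 0)) {
    stop("`E_values` must be nonnegative elbow stiffnesses")
  }
  bad <- setdiff(conditions, c("original", "constant", "inverse", "variable"))
  if (length(conditions) == 0 || length(bad) > 0) {
    stop("unknown conditions: ", paste(bad, collapse = ", "))
  }
  path_Es <- if (experiment == 1) E_values else path_E
  need <- union(path_Es, if ("variable" %in% conditions) donor_E)
  sims <- sims %||% list()
  for (E in need) {
    key <- as.character(E)
    if (is.null(sims[[key]])) {
      ctrl_E <- modify_ctrl_E(ctrl, E)
      sims[[key]] <- simulate_steady_cycle(params, ctrl_E, ...)
    }
  }
  geoms <- lapply(sims, path_geometry)
  donor <- if ("variable" %in% conditions) {
    key <- as.character(donor_E)
    retime_constant(sims[[key]], v_constant, geom = geoms[[key]])
  }
  grid <- tidyr::expand_grid(E = path_Es, condition = conditions)
  grid$trajectory <- purrr::pmap(grid, function(E, condition) {
    key <- as.character(E)
    traj <- sims[[key]]; geom <- geoms[[key]]
    switch(condition,
      original = retime_original(traj),
      constant = retime_constant(traj, v_constant, geom = geom),
      inverse = retime_inverse(traj, v = v_constant, geom = geom),
      variable = retime_variable(traj, donor)
    )
  })
  grid$duration <- purrr::map_dbl(grid$trajectory, attr, "duration")
  grid$loops <- ceiling(display_duration / grid$duration)
  tibble::tibble(
    experiment = experiment,
    grid[, c("E", "condition", "duration", "loops", "trajectory")]
  )
}

modify_ctrl_E <- function(ctrl, E) {
  controller_params(
    Kx = ctrl$Kx, Bx = ctrl$Bx, E = E, qr = ctrl$qr,
    circle_center = ctrl$circle_center, circle_radius = ctrl$circle_radius,
    period = ctrl$period, phase0 = ctrl$phase0
  )
}

time_column <- function(traj) {
  if ("t_new" %in% names(traj)) traj$t_new else traj$t
}
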