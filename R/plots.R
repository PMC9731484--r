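#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an endpoint path
#'
#' Endpoint path of one cycle with the controller's reference circle
#' overlaid (dashed) when available.
#'
#' @param object An `arm_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arm_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = if (!is.null(attr(object, "E"))) {
                    sprintf("Endpoint path, E = %g N m/rad", attr(object, "E"))
                  })
  ctrl <- attr(object, "ctrl")
  if (!is.null(ctrl)) {
    th <- seq(0, 2 * pi, length.out = 200)
    ref <- tibble::tibble(
      x = ctrl$circle_center[1] + ctrl$circle_radius * cos(th),
      y = ctrl$circle_center[2] + ctrl$circle_radius * sin(th)
    )
    p <- p + ggplot2::geom_path(data = ref, linetype = "dashed",
                                colour = "grey50")
  }
  p
}

#' Stimulus overview plots
#'
#' `plot_stimulus_paths()` overlays the endpoint paths of a stimulus set,
#' coloured by elbow stiffness. `plot_velocity_profiles()` shows the
#' tangential speed along each stimulus against its own time vector,
#' faceted by velocity-profile condition.
#'
#' @param stimuli A stimulus tibble from [build_stimulus_set()].
#' @return A ggplot object.
#' @export
plot_stimulus_paths <- function(stimuli) {
  one_per_path <- stimuli[!duplicated(stimuli$E), ]
  df <- purrr::map2_dfr(one_per_path$trajectory, one_per_path$E,
                        ~ dplyr::mutate(tibble::as_tibble(.x)[, c("x", "y")],
                                        E = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(.data$E))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "E (N m/rad)")
}

#' @rdname plot_stimulus_paths
#' @export
plot_velocity_profiles <- function(stimuli) {
  df <- purrr::pmap_dfr(
    stimuli[, c("trajectory", "E", "condition")],
    function(trajectory, E, condition) {
      v <- tangential_speed(trajectory)
      tt <- time_column(trajectory)[seq_along(v)]
      tibble::tibble(t = tt, speed = v, E = E, condition = condition)
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$speed,
                                   colour = factor(.data$E))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "tangential speed (m/s)",
                  colour = "E (N m/rad)")
}

#' Rating summary plot
#'
#' Mean rating (+/- 2 SE) against simulated elbow stiffness, one line per
#' velocity-profile condition — the standard summary of an Experiment 1
#' dataset. For Experiment 2 data (a single `E`) the x axis is the
#' condition instead.
#'
#' @param ratings A rating tibble from [generate_ratings()].
#' @return A ggplot object.
#' @export
plot_rating_summary <- function(ratings) {
  if (length(unique(ratings$E)) > 1) {
    df <- ratings |>
      dplyr::group_by(.data$condition, .data$E) |>
      dplyr::summarise(mean = mean(.data$rating),
                       se2 = 2 * stats::sd(.data$rating) / sqrt(dplyr::n()),
                       .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$E, y = .data$mean,
                                     colour = .data$condition)) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se2,
                                            ymax = .data$mean + .data$se2)) +
      ggplot2::labs(x = "simulated elbow stiffness E (N m/rad)",
                    y = "stiffness rating (1-7)", colour = "condition")
  } else {
    df <- ratings |>
      dplyr::group_by(.data$subject_id, .data$condition) |>
      dplyr::summarise(m = mean(.data$rating), .groups = "drop") |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean = mean(.data$m),
                       se2 = 2 * stats::sd(.data$m) / sqrt(dplyr::n()),
                       .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se2,
                                          ymax = .data$mean + .data$se2),
                             width = 0.2) +
      ggplot2::labs(x = "velocity profile", y = "stiffness rating (1-7)")
  }
}

#' Feature-versus-stiffness plot
#'
#' One panel per selected feature showing its value against elbow
#' stiffness for a feature table (original-condition rows are used for the
#' timing-invariant path features).
#'
#' @param features A feature table from [extract_features()].
#' @param which Character vector of feature column names.
#' @return A ggplot object.
#' @export
plot_features <- function(features,
                          which = c("oblongness", "area", "mean_curvature",
                                    "relative_phase", "shoulder_rom",
                                    "elbow_rom")) {
  df <- features[features$condition == "original",
                 c("E", intersect(which, names(features)))] |>
    tidyr::pivot_longer(-"E", names_to = "feature", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$E, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "simulated elbow stiffness E (N m/rad)", y = NULL)
}
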