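#' Trajectory CSV round trip
#'
#' Writes a (possibly retimed) trajectory to CSV — one row per sample,
#' columns `t`, `q1`, `q2`, `qd1`, `qd2`, `x`, `y`, `xd`, `yd` plus
#' `t_new`/`condition` when present — with a JSON sidecar (`<path>.json`)
#' recording column units and stimulus metadata. Numeric fields survive the
#' round trip at full double precision.
#'
#' @param traj A trajectory tibble.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- intersect(c("t", "q1", "q2", "qd1", "qd2", "x", "y", "xd", "yd",
                      "t_new", "condition"), names(traj))
  df <- as.data.frame(traj)[, cols]
  for (cl in setdiff(cols, "condition")) {
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  units <- c(t = "s", q1 = "rad", q2 = "rad", qd1 = "rad/s", qd2 = "rad/s",
             x = "m", y = "m", xd = "m/s", yd = "m/s", t_new = "s",
             condition = "")
  meta <- list(
    units = as.list(units[cols]),
    E = attr(traj, "E"),
    period = attr(traj, "period"),
    condition = attr(traj, "condition")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @param check_monotone Reject files whose time column is not strictly
#'   increasing.
#' @return `read_trajectory()` returns the trajectory tibble with `E`,
#'   `period` and `condition` attributes restored from the sidecar.
#' @export
read_trajectory <- function(path, check_monotone = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  need <- c("t", "q1", "q2", "qd1", "qd2", "x", "y", "xd", "yd")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("trajectory file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (check_monotone && any(diff(df$t) <= 0)) {
    stop("time column `t` is not strictly increasing")
  }
  if ("t_new" %in% names(df) && check_monotone && any(diff(df$t_new) <= 0)) {
    stop("time column `t_new` is not strictly increasing")
  }
  out <- tibble::as_tibble(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(out, "E") <- meta$E
    attr(out, "period") <- meta$period
    attr(out, "condition") <- meta$condition
  }
  class(out) <- unique(c("arm_trajectory", class(tibble::tibble())))
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one validated list:
#' arm anthropometrics, controller impedances and reference orbit, the
#' stimulus grid, the synthetic rater populations of both experiments, and
#' the master seed. `write_pipeline_config()` / `read_pipeline_config()`
#' round-trip the configuration through YAML losslessly; unknown keys are
#' rejected on construction and on read.
#'
#' @param arm Named list of [arm_params()] arguments to override.
#' @param controller Named list of [controller_params()] arguments to
#'   override (per-stimulus `E` comes from `E_values`).
#' @param E_values Elbow stiffness grid (N m/rad).
#' @param conditions Velocity-profile conditions.
#' @param v_constant Constant-condition speed (m/s).
#' @param display_duration Display time per stimulus (s).
#' @param path_E,donor_E Experiment 2 path stiffness and variable-condition
#'   donor stiffness (N m/rad).
#' @param subjects_exp1,subjects_exp2 Named lists of [subject_models()]
#'   arguments (including `n_subjects`) for each experiment.
#' @param seed Master integer seed.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(arm = list(),
                            controller = list(),
                            E_values = c(0, 10, 20, 30, 40, 50),
                            conditions = c("original", "constant",
                                           "inverse", "variable"),
                            v_constant = 0.185,
                            display_duration = 20,
                            path_E = 30,
                            donor_E = 50,
                            subjects_exp1 = list(n_subjects = 40),
                            subjects_exp2 = list(n_subjects = 10,
                                                 temporal_penalty = 0.8),
                            seed = 1L) {
  check_keys(arm, names(formals(arm_params)), "arm")
  check_keys(controller,
             setdiff(names(formals(controller_params)), c("E", "Kq")),
             "controller")
  sub_keys <- setdiff(names(formals(subject_models)), "seed")
  check_keys(subjects_exp1, sub_keys, "subjects_exp1")
  check_keys(subjects_exp2, sub_keys, "subjects_exp2")
  structure(
    list(arm = arm, controller = controller, E_values = E_values,
         conditions = conditions, v_constant = v_constant,
         display_duration = display_duration, path_E = path_E,
         donor_E = donor_E, subjects_exp1 = subjects_exp1,
         subjects_exp2 = subjects_exp2, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

check_keys <- function(x, allowed, what) {
  if (length(x) > 0 && (is.null(names(x)) || any(names(x) == ""))) {
    stop("all `", what, "` entries must be named")
  }
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    stop("unknown `", what, "` keys: ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` object.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, names(formals(pipeline_config)), "config")
  raw <- lapply(raw, function(x) if (is.list(x)) lapply(x, unlist_num) else unlist_num(x))
  do.call(pipeline_config, raw)
}

unlist_num <- function(x) {
  if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) unlist(x) else x
}

#' Run the full stimulus-to-report pipeline
#'
#' Simulates the steady-state cycles for every requested elbow stiffness,
#' assembles the Experiment 1 and 2 stimulus sets, extracts the feature
#' table, draws synthetic rater populations, generates blocked randomized
#' rating datasets, fits the per-subject regressions (Experiment 1), and
#' summarizes both experiments. All randomness derives from `config$seed`,
#' so a repeated run reproduces the ratings and report bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, features, ratings, fits
#'   and the report are written as CSV/JSON.
#' @param quiet Suppress progress messages.
#' @return A list: `stimuli` (per experiment), `features`, `subjects`,
#'   `ratings`, `fits` (Experiment 1), `report` (per experiment summaries).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  params <- do.call(arm_params, config$arm)
  ctrl <- do.call(controller_params, config$controller)

  need_E <- union(config$E_values, c(config$path_E, config$donor_E))
  sims <- list()
  for (E in need_E) {
    say("simulating steady cycle, E = ", E, " N m/rad")
    sims[[as.character(E)]] <-
      simulate_steady_cycle(params, modify_ctrl_E(ctrl, E))
  }
  common <- list(params = params, ctrl = ctrl,
                 conditions = config$conditions,
                 v_constant = config$v_constant,
                 path_E = config$path_E, donor_E = config$donor_E,
                 display_duration = config$display_duration, sims = sims)
  stim1 <- do.call(build_stimulus_set,
                   c(list(experiment = 1, E_values = config$E_values), common))
  stim2 <- do.call(build_stimulus_set, c(list(experiment = 2), common))
  features <- dplyr::bind_rows(extract_features(stim1),
                               extract_features(stim2))

  seed <- config$seed
  subj1 <- do.call(subject_models,
                   c(config$subjects_exp1, list(seed = seed + 101L)))
  subj2 <- do.call(subject_models,
                   c(config$subjects_exp2, list(seed = seed + 102L)))
  des1 <- build_design(1, nrow(subj1), E_values = config$E_values,
                       conditions = config$conditions, seed = seed + 201L)
  des2 <- build_design(2, nrow(subj2), conditions = config$conditions,
                       path_E = config$path_E, seed = seed + 202L)
  feat1 <- features[features$experiment == 1, ]
  feat2 <- features[features$experiment == 2, ]
  rat1 <- generate_ratings(des1, feat1, subj1, seed = seed + 301L)
  rat2 <- generate_ratings(des2, feat2, subj2, seed = seed + 302L)
  fits <- fit_subjects(rat1)
  report <- list(
    experiment1 = summarize_perception(rat1, fits, experiment = 1),
    experiment2 = summarize_perception(rat2, experiment = 2)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(dplyr::bind_rows(rat1, rat2),
                     file.path(out_dir, "ratings.csv"))
    readr::write_csv(tidy(fits), file.path(out_dir, "fits.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(stimuli = list(experiment1 = stim1, experiment2 = stim2),
       features = features,
       subjects = list(experiment1 = subj1, experiment2 = subj2),
       ratings = list(experiment1 = rat1, experiment2 = rat2),
       fits = fits, report = report)
}
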