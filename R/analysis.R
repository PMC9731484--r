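#' Per-subject linear fit of rating on simulated stiffness
#'
#' Fits, for every subject, the ordinary least-squares line
#' `rating = intercept + slope * E` and records the slope, the coefficient
#' of determination R^2 and the Pearson correlation. R^2 quantifies how
#' much of a subject's rating variance is explained by the simulated elbow
#' stiffness and is the study's per-subject performance measure. A subject
#' whose ratings are constant has zero regression sum of squares; R^2 (and
#' the correlation) are reported as 0 by convention.
#'
#' @param ratings A rating tibble (e.g. from [generate_ratings()]) with
#'   columns `subject_id`, `E`, `rating` and optionally `condition`,
#'   `experiment`. Every subject needs at least 3 trials covering at least
#'   2 distinct `E` values.
#' @return An object of class `perception_fit`: a tibble with one row per
#'   subject (`subject_id`, `condition`, `experiment`, `slope`,
#'   `intercept`, `r_squared`, `pearson_r`, `n`).
#' @seealso [tidy.perception_fit()], [glance.perception_fit()]
#' @export
fit_subjects <- function(ratings) {
  out <- purrr::map_dfr(split(ratings, ratings$subject_id), function(d) {
    if (nrow(d) < 3 || length(unique(d$E)) < 2) {
      stop("subject ", d$subject_id[1],
           ": need >= 3 trials over >= 2 distinct E values")
    }
    fit <- stats::lm(rating ~ E, data = d)
    sst <- sum((d$rating - mean(d$rating))^2)
    r2 <- if (sst < 1e-300) 0 else 1 - sum(stats::residuals(fit)^2) / sst
    r <- if (stats::sd(d$rating) < 1e-300) 0 else stats::cor(d$rating, d$E)
    tibble::tibble(
      subject_id = d$subject_id[1],
      condition = if ("condition" %in% names(d)) d$condition[1] else NA_character_,
      experiment = if ("experiment" %in% names(d)) d$experiment[1] else NA_integer_,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      pearson_r = r,
      n = nrow(d)
    )
  })
  structure(out, class = c("perception_fit", class(tibble::tibble())))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for perception fits
#'
#' `tidy()` returns the per-subject coefficient table; `glance()` returns a
#' one-row group summary (mean and SD of R^2 and slope over subjects).
#'
#' @param x A `perception_fit` object from [fit_subjects()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perception_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.perception_fit
#' @export
glance.perception_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x),
    mean_r_squared = mean(x$r_squared),
    sd_r_squared = stats::sd(x$r_squared),
    mean_slope = mean(x$slope),
    sd_slope = stats::sd(x$slope)
  )
}

#' @export
print.perception_fit <- function(x, ...) {
  cat("<perception_fit> ", nrow(x), " subjects; mean R^2 = ",
      signif(mean(x$r_squared), 3), ", mean slope = ",
      signif(mean(x$slope), 3), "\n", sep = "")
  print(tibble::as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Group-level summary of a rating dataset
#'
#' Condition-level descriptives and simple group tests:
#' * `ratings_by_E`: mean rating with +/- 2 SE per condition and stiffness.
#' * `r2_by_condition`, `slope_by_condition`: per-condition mean +/- 2 SE
#'   of the per-subject R^2 and slope (Experiment 1 format).
#' * `anova_r2`, `anova_slope`: one-way between-subjects ANOVA of R^2 and
#'   slope across conditions (F and p).
#' * For a within-subject (Experiment 2) dataset: `profile_means` (mean
#'   rating +/- 2 SE per velocity profile) and `paired_tests` (all pairwise
#'   paired t-tests on per-subject condition means, raw p-values, as
#'   planned comparisons).
#'
#' @param ratings A rating tibble with columns `subject_id`, `condition`,
#'   `E`, `rating`.
#' @param fits Optional [fit_subjects()] result; fitted on the fly when the
#'   dataset spans at least two `E` values.
#' @param experiment 1 (between-subject conditions, fits analyzed) or 2
#'   (within-subject velocity profiles, paired comparisons). Inferred from
#'   an `experiment` column when present.
#' @return A list of tibbles as described above.
#' @export
summarize_perception <- function(ratings, fits = NULL, experiment = NULL) {
  experiment <- experiment %||%
    (if ("experiment" %in% names(ratings)) ratings$experiment[1] else 1)
  se2 <- function(x) 2 * stats::sd(x) / sqrt(length(x))
  out <- list()
  out$ratings_by_E <- ratings |>
    dplyr::group_by(.data$condition, .data$E) |>
    dplyr::summarise(
      mean_rating = mean(.data$rating),
      se2 = se2(.data$rating),
      n = dplyr::n(), .groups = "drop"
    )

  if (experiment == 1) {
    if (is.null(fits)) fits <- fit_subjects(ratings)
    if (min(table(fits$condition)) < 2) {
      stop("need >= 2 subjects per condition for the between-subject ANOVA")
    }
    cond_stats <- function(v) {
      fits |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(mean = mean(.data[[v]]), se2 = se2(.data[[v]]),
                         n = dplyr::n(), .groups = "drop")
    }
    out$r2_by_condition <- cond_stats("r_squared")
    out$slope_by_condition <- cond_stats("slope")
    out$anova_r2 <- oneway_anova(fits$r_squared, fits$condition)
    out$anova_slope <- oneway_anova(fits$slope, fits$condition)
    out$fits <- tibble::as_tibble(unclass(fits))
  } else {
    subj_means <- ratings |>
      dplyr::group_by(.data$subject_id, .data$condition) |>
      dplyr::summarise(mean_rating = mean(.data$rating), .groups = "drop")
    out$profile_means <- subj_means |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean_rating = mean(.data$mean_rating),
                       se2 = se2(.data$mean_rating),
                       n = dplyr::n(), .groups = "drop")
    wide <- tidyr::pivot_wider(subj_means, names_from = "condition",
                               values_from = "mean_rating")
    conds <- setdiff(names(wide), "subject_id")
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    out$paired_tests <- purrr::map_dfr(pairs, function(p) {
      a <- wide[[p[1]]]; b <- wide[[p[2]]]
      if (stats::sd(a - b) < 1e-12) {
        tibble::tibble(condition_a = p[1], condition_b = p[2],
                       mean_diff = mean(a - b), t = 0, df = length(a) - 1,
                       p_value = 1)
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        tibble::tibble(condition_a = p[1], condition_b = p[2],
                       mean_diff = unname(tt$estimate),
                       t = unname(tt$statistic),
                       df = unname(tt$parameter),
                       p_value = tt$p.value)
      }
    })
  }
  out
}

oneway_anova <- function(y, group) {
  fit <- stats::aov(y ~ factor(group))
  tab <- summary(fit)[[1]]
  tibble::tibble(
    f = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
    df_between = tab[["Df"]][1], df_within = tab[["Df"]][2]
  )
}

#' Code a self-reported estimating strategy
#'
#' Classifies free-text strategy reports into four binary features by
#' case-insensitive whole-word (or phrase) keyword matching:
#' * path information: "distance", "displacement", "range of motion",
#'   "angle"
#' * temporal information: "speed", "rate", "acceleration", "jerk",
#'   "smooth"
#' * joint motion: "joint", "shoulder", "elbow", "angle"
#' * endpoint motion: "endpoint", "hand"
#'
#' "angle" sets both the path and joint flags (it appears in both
#' criteria). Picture-based reports cannot be coded from text.
#'
#' @param text Character vector of strategy reports (one per subject).
#' @return A tibble with columns `text`, `path_info`, `temporal_info`,
#'   `joint_motion`, `endpoint_motion` (logical), one row per input.
#' @examples
#' code_strategy("I watched the elbow angle and the speed of movement")
#' @export
code_strategy <- function(text) {
  stopifnot(is.character(text), all(nzchar(text)))
  kw <- list(
    path_info = c("distance", "displacement", "range of motion", "angle"),
    temporal_info = c("speed", "rate", "acceleration", "jerk", "smooth"),
    joint_motion = c("joint", "shoulder", "elbow", "angle"),
    endpoint_motion = c("endpoint", "hand")
  )
  match_any <- function(words, x) {
    pat <- paste0("\\b(", paste(words, collapse = "|"), ")\\b")
    grepl(pat, x, ignore.case = TRUE)
  }
  tibble::tibble(
    text = text,
    path_info = match_any(kw$path_info, text),
    temporal_info = match_any(kw$temporal_info, text),
    joint_motion = match_any(kw$joint_motion, text),
    endpoint_motion = match_any(kw$endpoint_motion, text)
  )
}
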