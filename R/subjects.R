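#' Synthetic rater population
#'
#' Builds a table of subject response models for the rating generator. Each
#' subject maps a standardized driving feature of the stimulus to a latent
#' stiffness estimate through an affine response, then degrades it with
#' additive noise, central-tendency shrinkage toward the scale midpoint,
#' and quantization to the bounded rating scale:
#'
#' `latent = intercept + gain * sign * z(feature) + penalty * [condition != original] + noise`
#'
#' The population is heterogeneous in `gain` (between-subject standard
#' deviation `gain_sd`), which is what spreads the per-subject regression
#' R^2 values below 1 even at low trial noise.
#'
#' @param n_subjects Number of subjects.
#' @param gain Mean response gain (rating units per SD of the driving
#'   feature).
#' @param gain_sd Between-subject SD of the gain.
#' @param intercept Latent rating at the feature mean (rating units).
#' @param noise_sd Trial-to-trial latent noise SD (rating units, applied
#'   before quantization).
#' @param central_tendency Shrinkage toward the scale midpoint 4, in
#'   `[0, 1]`; 1 collapses every rating to 4.
#' @param driving_feature Name of the feature column driving the response
#'   (e.g. `"elbow_rom"`, any [extract_features()] column, or `"E"` to read
#'   the simulated stiffness directly).
#' @param feature_sign +1 or -1; the default pairs `-1` with `elbow_rom`,
#'   encoding "stiffer-looking arms move the elbow less".
#' @param temporal_penalty Rating units added whenever the displayed
#'   condition is not `original` (the Experiment 2 effect: veridical
#'   velocity profiles are judged less stiff).
#' @param seed Optional integer seed for reproducible gain draws.
#' @return A tibble with one row per subject and the model columns.
#' @export
subject_models <- function(n_subjects,
                           gain = 1.5, gain_sd = 0.5,
                           intercept = 4, noise_sd = 0.8,
                           central_tendency = 0.1,
                           driving_feature = "elbow_rom",
                           feature_sign = -1,
                           temporal_penalty = 0,
                           seed = NULL) {
  stopifnot(n_subjects >= 1, noise_sd >= 0, gain_sd >= 0,
            central_tendency >= 0, central_tendency <= 1,
            feature_sign %in% c(-1, 1), temporal_penalty >= 0)
  draw <- function() {
    tibble::tibble(
      subject_id = seq_len(n_subjects),
      gain = stats::rnorm(n_subjects, gain, gain_sd),
      intercept = intercept,
      noise_sd = noise_sd,
      central_tendency = central_tendency,
      driving_feature = driving_feature,
      feature_sign = feature_sign,
      temporal_penalty = temporal_penalty
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Blocked, within-block-randomized trial schedule
#'
#' Emulates the experimental protocol: every subject rates each stimulus of
#' their set once per block, five times in total, with stimulus order
#' freshly randomized within each block. Experiment 1 varies elbow
#' stiffness (six values; 30 trials per subject) with the velocity-profile
#' condition assigned between subjects, balanced round-robin. Experiment 2
#' varies the velocity profile within subject on the fixed `path_E` path
#' (four conditions; 20 trials per subject).
#'
#' @param experiment 1 or 2.
#' @param n_subjects Number of subjects.
#' @param n_blocks Number of blocks (repetitions of each stimulus).
#' @param E_values Experiment 1 elbow stiffness values (N m/rad).
#' @param conditions Velocity-profile conditions.
#' @param path_E Experiment 2 path stiffness (N m/rad).
#' @param seed Optional integer seed; the same seed reproduces the schedule
#'   exactly.
#' @return A tibble with columns `subject_id`, `experiment`, `condition`,
#'   `E`, `block`, `trial_index`.
#' @export
build_design <- function(experiment, n_subjects, n_blocks = 5,
                         E_values = c(0, 10, 20, 30, 40, 50),
                         conditions = c("original", "constant",
                                        "inverse", "variable"),
                         path_E = 30,
                         seed = NULL) {
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  stopifnot(n_subjects >= 1)
  build <- function() {
    purrr::map_dfr(seq_len(n_subjects), function(sid) {
      if (experiment == 1) {
        cond <- conditions[(sid - 1) %% length(conditions) + 1]
        stim <- tibble::tibble(condition = cond, E = E_values)
      } else {
        stim <- tibble::tibble(condition = conditions, E = path_E)
      }
      blocks <- purrr::map_dfr(seq_len(n_blocks), function(b) {
        perm <- stim[sample.int(nrow(stim)), ]
        perm$block <- b
        perm
      })
      blocks$subject_id <- sid
      blocks$experiment <- experiment
      blocks$trial_index <- seq_len(nrow(blocks))
      blocks[, c("subject_id", "experiment", "condition", "E",
                 "block", "trial_index")]
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate synthetic Likert ratings
#'
#' Applies each subject's response model to their scheduled stimuli. The
#' driving feature is standardized within subject over the distinct stimuli
#' that subject rates (z = 0 everywhere if the feature does not vary, as
#' for path features in Experiment 2). The latent estimate is shrunk toward
#' the midpoint 4 by the subject's central-tendency factor and quantized to
#' the nearest of `n_levels` evenly spaced response options spanning
#' `[1, 7]`; the default 7 levels are the integers 1-7. Coarser scales
#' (fewer levels) produce larger quantization error, finer scales smaller.
#'
#' @param design A schedule from [build_design()].
#' @param features A feature table from [extract_features()] (may be `NULL`
#'   when every subject's `driving_feature` is `"E"`).
#' @param subjects A subject table from [subject_models()].
#' @param n_levels Number of response options on the `[1, 7]` scale.
#' @param seed Optional integer seed; ratings are reproducible bit-for-bit
#'   under a fixed seed.
#' @return The design tibble plus columns `latent` (pre-quantization
#'   estimate, diagnostic) and `rating`.
#' @export
generate_ratings <- function(design, features = NULL, subjects,
                             n_levels = 7, seed = NULL) {
  stopifnot(n_levels >= 2)
  run <- function() {
    out <- purrr::map_dfr(split(design, design$subject_id), function(d) {
      sub <- subjects[subjects$subject_id == d$subject_id[1], ]
      f <- stimulus_feature(d, features, sub$driving_feature)
      stim <- unique(f)
      zsd <- stats::sd(stim)
      z <- if (is.na(zsd) || zsd < 1e-12) rep(0, nrow(d)) else (f - mean(stim)) / zsd
      latent <- sub$intercept + sub$gain * sub$feature_sign * z +
        sub$temporal_penalty * (d$condition != "original") +
        stats::rnorm(nrow(d), 0, sub$noise_sd)
      shrunk <- 4 + (1 - sub$central_tendency) * (latent - 4)
      levels <- seq(1, 7, length.out = n_levels)
      d$latent <- latent
      d$rating <- levels[pmax(1, pmin(n_levels, round((shrunk - 1) / 6 * (n_levels - 1)) + 1))]
      d
    })
    out[order(out$subject_id, out$trial_index), ]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

stimulus_feature <- function(d, features, driving_feature) {
  if (driving_feature == "E") return(d$E)
  if (is.null(features) || !driving_feature %in% names(features)) {
    stop("unknown driving feature: ", driving_feature)
  }
  key <- paste(d$E, d$condition)
  fkey <- paste(features$E, features$condition)
  idx <- match(key, fkey)
  if (anyNA(idx)) {
    stop("schedule contains stimuli with no feature row: ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  features[[driving_feature]][idx]
}

#' Template strategy texts for the self-report coder
#'
#' Assembles a short self-report from fixed template sentences so that the
#' text contains keywords for exactly the requested feature categories
#' (path information, temporal information, joint motion, endpoint motion).
#' Used to exercise [code_strategy()] against known ground truth.
#'
#' @param path_info,temporal_info,joint_motion,endpoint_motion Logical.
#' @param seed Optional integer seed for keyword choice.
#' @return A single character string.
#' @export
generate_strategy_text <- function(path_info = FALSE, temporal_info = FALSE,
                                   joint_motion = FALSE,
                                   endpoint_motion = FALSE,
                                   seed = NULL) {
  pick <- function(x) x[sample.int(length(x), 1)]
  build <- function() {
    s <- character(0)
    # keywords chosen from the single-category lists so flags do not leak
    if (path_info) {
      s <- c(s, sprintf("I looked at the %s covered by the arm.",
                        pick(c("distance", "displacement", "range of motion"))))
    }
    if (temporal_info) {
      s <- c(s, sprintf("The %s of the movement mattered to me.",
                        pick(c("speed", "rate", "acceleration", "jerk"))))
    }
    if (joint_motion) {
      s <- c(s, sprintf("I watched how much the %s moved.",
                        pick(c("joint", "shoulder", "elbow"))))
    }
    if (endpoint_motion) {
      s <- c(s, sprintf("I followed the %s of the figure.",
                        pick(c("endpoint", "hand"))))
    }
    if (length(s) == 0) s <- "It just looked more or less rigid to me."
    paste(s, collapse = " ")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
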