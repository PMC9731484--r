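test_that("per-subject fits match hand-checkable cases", {
  d <- tibble::tibble(subject_id = 1, E = c(0, 10, 20, 30, 40, 50),
                      rating = 1:6)
  fit <- fit_subjects(d)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 6)

  d$rating <- rep(4, 6)
  fit <- fit_subjects(d)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)

  expect_error(fit_subjects(tibble::tibble(subject_id = 1, E = c(1, 1, 1),
                                           rating = c(1, 2, 3))),
               "distinct E")
})

test_that("fits agree with the closed-form normal equations", {
  set.seed(71)
  d <- tibble::tibble(subject_id = 1,
                      E = rep(c(0, 10, 20, 30, 40, 50), 5),
                      rating = sample(1:7, 30, replace = TRUE))
  fit <- fit_subjects(d)
  # independent least-squares oracle
  X <- cbind(1, d$E)
  beta <- solve(t(X) %*% X, t(X) %*% d$rating)
  res <- d$rating - X %*% beta
  r2 <- 1 - sum(res^2) / sum((d$rating - mean(d$rating))^2)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit table and its group summary", {
  set.seed(72)
  d <- tidyr::expand_grid(subject_id = 1:6, E = c(0, 10, 20, 30, 40, 50))
  d$rating <- pmax(1, pmin(7, round(2 + d$E / 15 + rnorm(nrow(d), 0, 0.7))))
  fits <- fit_subjects(d)
  td <- tidy(fits)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  gl <- glance(fits)
  expect_equal(gl$n_subjects, 6)
  expect_equal(gl$mean_r_squared, mean(td$r_squared))
})

test_that("the between-subject ANOVA matches the textbook oracle", {
  set.seed(73)
  fits <- tibble::tibble(
    subject_id = 1:20,
    condition = rep(c("original", "constant", "inverse", "variable"), 5),
    r_squared = runif(20), slope = rnorm(20, 0.5, 0.2)
  )
  class(fits) <- c("perception_fit", class(tibble::tibble()))
  ratings <- tibble::tibble(subject_id = rep(1:20, each = 6),
                            condition = rep(fits$condition, each = 6),
                            E = rep(c(0, 10, 20, 30, 40, 50), 20),
                            rating = sample(1:7, 120, replace = TRUE))
  s <- summarize_perception(ratings, fits, experiment = 1)
  # textbook one-way ANOVA computed from group means and variances
  g <- split(fits$r_squared, fits$condition)
  grand <- mean(fits$r_squared)
  ssb <- sum(sapply(g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / (length(g) - 1)) / (ssw / (20 - length(g)))
  expect_equal(s$anova_r2$f, f_oracle, tolerance = 1e-10)
  expect_equal(s$anova_r2$df_between, 3)
  expect_equal(s$anova_r2$df_within, 16)

  # identical groups: zero between-group variance, F = 0
  fits2 <- fits
  fits2$r_squared <- ave(seq_len(20), fits$condition, FUN = seq_along) / 10
  s2 <- summarize_perception(ratings, fits2, experiment = 1)
  expect_equal(s2$anova_r2$f, 0, tolerance = 1e-12)
})

test_that("experiment 2 summaries include paired comparisons", {
  set.seed(74)
  d <- tidyr::expand_grid(subject_id = 1:8,
                          condition = c("original", "constant",
                                        "inverse", "variable"),
                          block = 1:5)
  d$E <- 30
  d$experiment <- 2
  d$rating <- pmax(1, pmin(7, round(4 + 0.8 * (d$condition != "original") +
                                      rnorm(nrow(d), 0, 0.5))))
  s <- summarize_perception(d, experiment = 2)
  expect_equal(nrow(s$profile_means), 4)
  expect_equal(nrow(s$paired_tests), 6)
  expect_true(all(s$paired_tests$p_value >= 0 & s$paired_tests$p_value <= 1))

  # paired identical samples give t = 0
  d$rating <- 4
  s0 <- summarize_perception(d, experiment = 2)
  expect_true(all(s0$paired_tests$t == 0))
  expect_true(all(s0$paired_tests$p_value == 1))
})

test_that("R^2 recovery degrades monotonically with rater noise", {
  des <- build_design(1, 60, seed = 81)
  mean_r2 <- sapply(c(0.3, 1.0, 2.5), function(ns) {
    subj <- subject_models(60, gain = 1.5, gain_sd = 0, noise_sd = ns,
                           central_tendency = 0, driving_feature = "E",
                           feature_sign = 1, seed = 82)
    rat <- generate_ratings(des, NULL, subj, seed = 83)
    mean(fit_subjects(rat)$r_squared)
  })
  expect_true(all(diff(mean_r2) < 0))
})

test_that("the generating slope is recovered from synthetic raters", {
  # heterogeneous population (the generator default): the between-subject
  # slope SD, not quantization ripple, sets the recovery error bar
  n <- 50
  gain <- 1.5
  subj <- subject_models(n, gain = gain, gain_sd = 0.5, noise_sd = 0.5,
                         central_tendency = 0, driving_feature = "E",
                         feature_sign = 1, seed = 91)
  des <- build_design(1, n, seed = 92)
  rat <- generate_ratings(des, NULL, subj, seed = 93)
  fits <- fit_subjects(rat)
  slope_gen <- gain / stats::sd(c(0, 10, 20, 30, 40, 50))
  se <- stats::sd(fits$slope) / sqrt(n)
  expect_lt(abs(mean(fits$slope) - slope_gen), 2 * se)
})

test_that("the strategy coder applies the keyword criteria", {
  got <- code_strategy("I watched the elbow angle and the speed of movement")
  expect_true(got$path_info && got$temporal_info && got$joint_motion)
  expect_false(got$endpoint_motion)

  got <- code_strategy("It just looked rigid")
  expect_false(any(unlist(got[, -1])))

  got <- code_strategy("the hand's displacement was smooth")
  expect_true(got$path_info && got$temporal_info && got$endpoint_motion)
  expect_false(got$joint_motion)

  # whole-word matching: no substring hits
  got <- code_strategy("an accurate, handsome but jerky rendering of angles")
  expect_false(got$path_info)      # "angles" != "angle"
  expect_false(got$endpoint_motion) # "handsome" != "hand"
  expect_false(got$temporal_info)   # "accurate" != "rate"; "jerky" != "jerk"

  expect_error(code_strategy(""), "nzchar")
})

test_that("the strategy coder is idempotent and order-invariant", {
  sentences <- c("I watched the elbow.", "The speed mattered.",
                 "The distance covered was key.")
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  codes <- lapply(perms, function(p) {
    code_strategy(paste(sentences[p], collapse = " "))[, -1]
  })
  expect_identical(codes[[1]], codes[[2]])
  expect_identical(codes[[1]], codes[[3]])
  twice <- code_strategy(paste(rep(sentences, 2), collapse = " "))[, -1]
  expect_identical(twice, codes[[1]])
})
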