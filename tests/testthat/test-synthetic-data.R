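test_that("ground-truth pattern has the requested sparsity and is seeded", {
  pat <- make_ground_truth_pattern(1000, active_fraction = 0.1, seed = 7)
  expect_equal(sum(pat$weights != 0), 100)
  expect_true(all(pat$weights[-pat$active] == 0))
  expect_identical(make_ground_truth_pattern(1000, 0.1, seed = 7)$weights,
                   pat$weights)
  # degenerate: zero effect scale gives an all-zero pattern
  flat <- make_ground_truth_pattern(10, 1.0, effect_scale = 0, seed = 1)
  expect_true(all(flat$weights == 0))
  expect_error(make_ground_truth_pattern(0), "n_voxels")
  expect_error(make_ground_truth_pattern(10, active_fraction = 0),
               "active_fraction")
})

test_that("volume counts follow session duration, TR, and dummy discard", {
  # a 21.9-minute session at TR 2 s: 657 retained volumes, 662 acquired
  # including the 5 discarded dummies (21.9 * 60 / 2 = 657)
  s <- make_toy_sequence(plateau_onsets = c(20, 60), session_duration = 21.9 * 60)
  pat <- make_ground_truth_pattern(10, seed = 1)
  run <- simulate_bold_run(s, pat, noise_sd = 0, ar1_rho = 0, seed = 1)
  expect_equal(nrow(run$data), 657)
  expect_equal(run$n_acquired, 662)
  expect_equal(nrow(run$motion_params), nrow(run$data))
})

test_that("simulated AR(1) noise has the planted lag-1 autocorrelation", {
  s <- make_toy_sequence(plateau_onsets = 20, session_duration = 1300)
  pat <- make_ground_truth_pattern(40, effect_scale = 0, seed = 2)
  run <- simulate_bold_run(s, pat, noise_sd = 1, ar1_rho = 0.3, seed = 5)
  centered <- scale(run$data, scale = FALSE)
  n <- nrow(centered)
  rho_hat <- sum(centered[-1, ] * centered[-n, ]) / sum(centered^2)
  expect_lt(abs(rho_hat - 0.3), 0.05)
})

test_that("training study is balanced, linear in temperature without noise, and seeded", {
  pat <- make_ground_truth_pattern(120, seed = 3)
  ts <- simulate_training_study(12, pattern = pat, seed = 4)
  expect_length(ts$subjects, 12)
  expect_equal(sum(vapply(ts$subjects, function(s) nrow(s$values), 1L)), 96)
  expect_length(ts$temp_levels, 8)
  expect_identical(simulate_training_study(12, pattern = pat, seed = 4), ts)

  ts0 <- simulate_training_study(3, pattern = pat, noise_sd = 0,
                                 subject_sd = 0, seed = 4) |>
    suppressWarnings()
  for (sub in ts0$subjects) {
    dT <- diff(ts0$temp_levels)
    dB <- diff(sub$values)
    # per-voxel beta differences equal pattern weight x delta-degC
    expect_lt(max(abs(dB - outer(dT, pat$weights))), 1e-8)
  }
  expect_error(simulate_training_study(2, pattern = pat), ">= 3 subjects")
  expect_warning(simulate_training_study(4, pattern = pat, seed = 1),
                 "few LOSO folds")
})

test_that("test study has 24 conditions per subject and picture-neutral expectation", {
  pat <- make_ground_truth_pattern(100, seed = 6)
  te <- simulate_test_study(30, pattern = pat, seed = 6)
  expect_length(te$subjects, 30)
  expect_true(all(vapply(te$subjects, function(s) nrow(s$values), 1L) == 24))
  expect_equal(nrow(te$design), 24)

  # without modulation and noise, the pattern dot product is identical across
  # picture conditions at a fixed temperature
  te0 <- simulate_test_study(2, pattern = pat, noise_sd = 0, subject_sd = 0,
                             seed = 1)
  proj <- te0$subjects[[1]]$values %*% pat$weights
  for (tmp in unique(te0$design$temperature)) {
    expect_lt(diff(range(proj[te0$design$temperature == tmp])), 1e-10)
  }
})

test_that("pattern-aligned modulation raises the targeted condition's estimate", {
  pat <- make_ground_truth_pattern(300, seed = 8)
  mod <- list(cells = c("oxytocin|47.1|negative" = 5), mode = "aligned")
  te <- simulate_test_study(8, pattern = pat, noise_sd = 0.2, subject_sd = 0,
                            modulation = mod, seed = 9)
  # brute-force dot product with the true pattern, per condition
  w <- pat$weights / sqrt(sum(pat$weights^2))
  scores <- vapply(te$subjects, function(s) drop(s$values %*% w),
                   numeric(24))
  mean_by_cond <- rowMeans(scores)
  at47 <- te$design$temperature == 47.1
  target <- te$design$medication == "oxytocin" & at47 &
    te$design$picture == "negative"
  expect_true(mean_by_cond[target] >
                max(mean_by_cond[at47 & !target]) + 1)
  expect_error(
    simulate_test_study(3, pattern = pat, seed = 1,
                        modulation = list(cells = c(nonsense = 1))),
    "unknown modulation cell")
})

test_that("ratings reproduce planted cell means exactly when noise-free", {
  cfg_i <- rating_effects_config("intensity", sd_subject_intercept = 0,
                                 sd_subject_slope = 0, sd_residual = 0)
  cfg_u <- rating_effects_config("unpleasantness", sd_subject_intercept = 0,
                                 sd_subject_slope = 0, sd_residual = 0)
  rt <- simulate_ratings(cfg_i, cfg_u, n_subjects = 2, truncate = FALSE,
                         seed = 1)
  agg <- aggregate_conditions(rt)
  # noxious - non-noxious across the analysis cells equals the planted 47.8
  # (intensity) and 50.1 (unpleasantness) VAS
  sel <- agg$picture != "scrambled"
  m <- function(col, temp) mean(agg[sel & agg$temperature == temp, col])
  expect_equal(m("intensity", 47.1) - m("intensity", 44.7), 47.8)
  expect_equal(m("unpleasantness", 47.1) - m("unpleasantness", 44.7), 50.1)
  # three-way structure: negative - positive at noxious heat per medication
  np <- function(med) {
    r <- agg[agg$temperature == 47.1 & agg$medication == med, ]
    mean(r$unpleasantness[r$picture == "negative"]) -
      mean(r$unpleasantness[r$picture == "positive"])
  }
  expect_equal(np("oxytocin"), 7.08)
  expect_equal(np("placebo"), 3.26)
})

test_that("ratings are truncated to the VAS range and seeded", {
  rt <- simulate_ratings(n_subjects = 12, seed = 2)
  expect_true(all(rt$intensity >= 0 & rt$intensity <= 100))
  expect_true(all(rt$unpleasantness >= 0 & rt$unpleasantness <= 100))
  expect_identical(simulate_ratings(n_subjects = 12, seed = 2), rt)
  expect_equal(nrow(rt), 12 * 2 * 36)
})

test_that("psychometric pain classification matches the planted proportions", {
  # Monte-Carlo at n = 10^4 trials per temperature, fixed seed
  cfg <- rating_effects_config("intensity")
  set.seed(99)
  p <- function(temp) {
    mean(stats::rbinom(1e4, 1,
                       stats::plogis((temp - cfg$pain_midpoint) /
                                       cfg$pain_scale)))
  }
  expect_equal(p(35.0), 0)                  # never painful at baseline
  expect_lt(abs(p(44.7) - 0.031), 0.01)
  expect_lt(abs(p(47.1) - 0.836), 0.01)
})
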