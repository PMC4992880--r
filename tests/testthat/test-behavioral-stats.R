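test_that("outlier threshold and flags implement the 1:5000 two-tailed rule", {
  set.seed(30)
  g <- data.frame(subject = "s1", temperature = 47.1,
                  intensity = c(rnorm(50), 10))
  rep1 <- flag_outliers(g, "intensity")
  expect_equal(rep1$threshold, 3.71901649, tolerance = 1e-6)
  expect_equal(rep1$index, 51L)
  expect_equal(nrow(rep1$flagged), 1)

  # data bounded inside |z| < 3 can never be flagged
  set.seed(31)
  bounded <- data.frame(subject = rep(c("a", "b"), each = 30),
                        temperature = 44.7,
                        intensity = pmin(pmax(rnorm(60), -2.9), 2.9))
  expect_equal(length(flag_outliers(bounded, "intensity")$index), 0)

  # degenerate all-identical group is skipped, not flagged
  flat <- data.frame(subject = "s", temperature = 35, intensity = rep(4, 5))
  expect_warning(repf <- flag_outliers(flat, "intensity"), "skipped")
  expect_equal(length(repf$index), 0)
  expect_error(flag_outliers(flat, "nonsense"), "unknown measure")

  # leave-one-out variant flags the same planted point
  rep_loo <- flag_outliers(g, "intensity", leave_one_out = TRUE)
  expect_true(51L %in% rep_loo$index)
})

test_that("aggregation averages surviving repetitions per design cell", {
  t3 <- data.frame(subject = "s1", medication = "placebo",
                   temperature = 47.1, picture = "neutral",
                   intensity = c(10, 20, 30))
  expect_equal(aggregate_conditions(t3)$intensity, 20)
  expect_equal(aggregate_conditions(t3[-2, ])$intensity, 20)

  rt <- simulate_ratings(n_subjects = 3, seed = 32)
  agg <- aggregate_conditions(rt)
  # 12 cells per subject-session: one row per subject x medication x cell
  expect_equal(nrow(agg), 3 * 2 * 12)
  expect_true(all(table(agg$subject, agg$medication) == 12))
})

test_that("outcome standardization is exact and invertible", {
  z <- standardize_outcome(c(0, 10))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2))
  expect_equal(attr(z, "scale") * as.numeric(z) + attr(z, "center"),
               c(0, 10))
  expect_error(standardize_outcome(rep(5, 4)), "zero SD")
})

test_that("with no subject variance the mixed fit reduces to OLS", {
  cfg_i <- rating_effects_config("intensity", sd_subject_intercept = 0,
                                 sd_subject_slope = 0, sd_residual = 8)
  rt <- simulate_ratings(cfg_i, n_subjects = 10, truncate = FALSE, seed = 33)
  agg <- aggregate_conditions(rt)
  fit <- fit_factorial_lmm(agg, "intensity", random = "intercept",
                           ddf = "Satterthwaite")
  d <- fit$data
  ols <- stats::lm(.z ~ .med * .temp * .val, data = d,
                   contrasts = list(.med = "contr.sum", .temp = "contr.sum",
                                    .val = "contr.sum"))
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 1e-4)
})

test_that("Type III F of a two-level factor equals the squared contrast t", {
  rt <- simulate_ratings(n_subjects = 10, seed = 34)
  agg <- aggregate_conditions(rt)
  fit <- fit_factorial_lmm(agg, "intensity", random = "intercept",
                           ddf = "Satterthwaite")
  mm <- marginal_means_contrasts(fit, "temperature")
  t_contrast <- mm$contrasts$beta / mm$contrasts$se_beta
  F_temp <- fit$anova$F[fit$anova$term == "temperature"]
  expect_equal(unname(t_contrast^2), F_temp, tolerance = 1e-6)
})

test_that("balanced-design marginal means equal raw cell means", {
  rt <- simulate_ratings(n_subjects = 8, seed = 35)
  agg <- aggregate_conditions(rt)
  fit <- fit_factorial_lmm(agg, "intensity", random = "intercept",
                           ddf = "Satterthwaite")
  mm <- marginal_means_contrasts(fit, "medication:temperature:valence")
  d <- fit$data
  cell <- stats::aggregate(d[[fit$outcome]],
                           by = list(medication = d$.med, temperature = d$.temp,
                                     valence = d$.val), FUN = mean)
  merged <- merge(mm$means, cell,
                  by = c("medication", "temperature", "valence"))
  expect_equal(merged$mean, merged$x, tolerance = 1e-6)
  # a cell contrasted with itself is zero with a covering interval
  expect_error(marginal_means_contrasts(fit, "nonsense"), "unknown term")
})

test_that("analysis chain is invariant to row shuffling", {
  rt <- simulate_ratings(n_subjects = 6, seed = 36)
  agg1 <- aggregate_conditions(rt)
  set.seed(1)
  agg2 <- aggregate_conditions(rt[sample(nrow(rt)), ])
  f1 <- fit_factorial_lmm(agg1, "intensity", random = "intercept",
                          ddf = "Satterthwaite")
  f2 <- fit_factorial_lmm(agg2, "intensity", random = "intercept",
                          ddf = "Satterthwaite")
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-8)
})

test_that("planted marginal effects are recovered by the mixed model", {
  rt <- simulate_ratings(n_subjects = 30, truncate = FALSE, seed = 37)
  agg <- aggregate_conditions(rt)
  fit_i <- fit_factorial_lmm(agg, "intensity")
  mm <- marginal_means_contrasts(fit_i, "temperature")
  # noxious - non-noxious contrast covers the planted 47.8 VAS
  lo <- -mm$contrasts$upper; hi <- -mm$contrasts$lower  # sign: non-nox - nox
  expect_true(lo <= 47.8 && 47.8 <= hi)

  fit_u <- fit_factorial_lmm(agg, "unpleasantness")
  m3 <- marginal_means_contrasts(fit_u, "medication:temperature:valence")
  ct <- m3$contrasts
  pick <- function(a, b) {
    ct[grepl(a, ct$contrast, fixed = TRUE) &
         grepl(b, ct$contrast, fixed = TRUE), ]
  }
  np_oxt <- pick("oxytocin noxious negative", "oxytocin noxious positive")
  expect_equal(nrow(np_oxt), 1)
  expect_true(np_oxt$lower <= 7.08 && 7.08 <= np_oxt$upper)
  np_pla <- pick("placebo noxious negative", "placebo noxious positive")
  expect_true(np_pla$lower <= 3.26 && 3.26 <= np_pla$upper)
})

test_that("control analyses recode, restrict, and count as specified", {
  rt <- simulate_ratings(n_subjects = 8, seed = 38)
  agg <- aggregate_conditions(rt)

  sc <- control_analyses(agg, "scrambled_factor", outcome = "intensity",
                         random = "intercept", ddf = "Satterthwaite")
  expect_s3_class(sc, "mixed_model_result")
  expect_true(any(grepl("valence", sc$anova$term)))
  lv <- levels(sc$data$.val)
  expect_setequal(lv, c("pictures", "scrambled"))
  # baseline-temperature rows are excluded by the model, scrambled rows kept
  expect_equal(sum(sc$data$.val == "scrambled"),
               sum(agg$picture == "scrambled" & agg$temperature != 35.0))

  bl <- control_analyses(agg, "baseline_only", outcome = "intensity")
  expect_true(all(bl$data$temperature == 35.0))

  pp <- control_analyses(rt, "pain_proportions")
  # brute-force count of the binary column
  for (i in seq_len(nrow(pp))) {
    sel <- rt$temperature == pp$temperature[i]
    expect_equal(pp$n_painful[i], sum(rt$pain_binary[sel]))
    expect_equal(pp$pct_painful[i], 100 * mean(rt$pain_binary[sel]))
  }
  expect_equal(pp$pct_painful[pp$temperature == 35.0], 0)
  expect_error(control_analyses(rt, "nonsense"))
})
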