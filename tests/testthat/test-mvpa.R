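test_that("voxelwise z-transform standardizes, records degenerate voxels, and round-trips", {
  zs <- zscore_voxelwise(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(zs$z[, 1]), c(-1, 0, 1))
  expect_equal(unname(zs$z[, 2]), c(0, 0, 0))
  expect_equal(zs$params$zero_variance, 2L, ignore_attr = TRUE)
  set.seed(1)
  M <- matrix(rnorm(60), 10, 6)
  zs2 <- zscore_voxelwise(M)
  expect_equal(unname(colMeans(zs2$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(zs2$z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  expect_identical(apply_standardization(M, zs2$params), zs2$z)
  expect_error(zscore_voxelwise(M[1, , drop = FALSE]), ">= 2 observations")
})

test_that("PCA keeps the smallest component count reaching the variance target", {
  # construct data whose sample covariance eigenvalues are exactly
  # (9, 0.9, 0.09, 1e-6): cumulative shares 0.9009 -> 0.9910 -> 0.99999,
  # so a 0.999 target needs 3 components
  ev <- c(9, 0.9, 0.09, 1e-6)
  H <- stats::contr.helmert(6)[, 1:4]
  S <- sweep(H, 2, apply(H, 2, sd), "/")
  S <- sweep(S, 2, sqrt(ev), "*")
  expect_equal(diag(stats::cov(S)), ev, ignore_attr = TRUE)  # fixture sanity
  res <- fit_pca(S, variance_target = 0.999)
  expect_equal(ncol(res$basis$rotation), 3)
  shares <- res$basis$variance_shares
  expect_equal(cumsum(shares)[3], sum(ev[1:3]) / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(shares) <= 0))

  # full-variance target reconstructs the data
  set.seed(2)
  M <- matrix(rnorm(8 * 5), 8, 5)
  r <- fit_pca(M, variance_target = 1)
  rec <- r$scores %*% t(r$basis$rotation) +
    matrix(r$basis$center, 8, 5, byrow = TRUE)
  expect_lt(max(abs(rec - M)), 1e-8)
  # scores are uncorrelated
  cc <- crossprod(scale(r$scores, scale = FALSE))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("elastic net matches least squares at lambda 0 and shrinks to the mean", {
  set.seed(3)
  Z <- matrix(rnorm(40 * 5), 40, 5)
  y <- drop(Z %*% c(2, 0, -1, 0.5, 0)) + rnorm(40, sd = 0.3)
  f0 <- fit_elastic_net(Z, y, alpha = 1, lambda = 0)
  ls <- stats::lm.fit(cbind(1, Z), y)$coefficients
  expect_equal(f0$weights, unname(ls[-1]), tolerance = 1e-6)
  expect_equal(f0$intercept, unname(ls[1]), tolerance = 1e-6)
  fbig <- fit_elastic_net(Z, y, alpha = 1, lambda = 1e4)
  expect_true(all(fbig$weights == 0))
  expect_equal(fbig$intercept, mean(y))
  expect_error(fit_elastic_net(Z, y, alpha = 0, lambda = 1), "alpha")
})

test_that("coordinate descent agrees with the naive oracle and with glmnet", {
  set.seed(4)
  for (i in 1:5) {
    Z <- matrix(rnorm(40 * 5), 40, 5)
    y <- drop(Z %*% rnorm(5)) + rnorm(40)
    for (alpha in c(0.3, 1)) {
      for (lambda in c(0.05, 0.5)) {
        f <- fit_elastic_net(Z, y, alpha, lambda)
        o <- oracle_enet_cd(Z, y, alpha, lambda)
        obj_f <- oracle_enet_objective(Z, y, f$weights, f$intercept,
                                       alpha, lambda)
        obj_o <- oracle_enet_objective(Z, y, o$weights, o$intercept,
                                       alpha, lambda)
        expect_lt(abs(obj_f - obj_o), 1e-6)
        if (alpha == 1) {
          # independent lasso cross-check; for alpha < 1 glmnet scales the
          # ridge term by the internal response standardization, so only the
          # pure-L1 case shares our parameterization exactly
          g <- glmnet::glmnet(Z, y, alpha = 1, lambda = lambda,
                              standardize = FALSE, thresh = 1e-14)
          expect_equal(f$weights, unname(as.numeric(g$beta)),
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("sparsity is non-increasing in lambda at fixed alpha", {
  set.seed(5)
  Z <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(Z %*% c(rep(1, 3), rep(0, 7))) + rnorm(30, sd = 0.5)
  lams <- 10^seq(-3, 1, length.out = 12)
  nz <- vapply(lams, function(l) fit_elastic_net(Z, y, 1, l)$n_nonzero, 1L)
  expect_true(all(diff(nz[order(lams)]) <= 0))
})

test_that("back-projection reproduces component-space predictions exactly", {
  set.seed(6)
  M <- matrix(rnorm(12 * 50), 12, 50)
  res <- fit_pca(M, 1)
  wc <- rnorm(ncol(res$basis$rotation))
  wv <- backproject(wc, res$basis)
  # explicit per-voxel loop oracle for the matrix product
  wv_loop <- numeric(50)
  for (v in 1:50) {
    acc <- 0
    for (k in seq_along(wc)) acc <- acc + res$basis$rotation[v, k] * wc[k]
    wv_loop[v] <- acc
  }
  expect_equal(wv, wv_loop, tolerance = 1e-12, ignore_attr = TRUE)
  # prediction identity on fresh random maps
  X <- matrix(rnorm(20 * 50), 20, 50)
  pred_comp <- 0.7 + project_pca(X, res$basis) %*% wc
  pred_vox <- 0.7 + sweep(X, 2, res$basis$center, "-") %*% wv
  expect_lt(max(abs(pred_comp - pred_vox)), 1e-10)
  # a single-component basis back-projects proportionally to its loading
  b1 <- res$basis
  b1$rotation <- b1$rotation[, 1, drop = FALSE]
  expect_equal(backproject(2, b1), 2 * b1$rotation[, 1], ignore_attr = TRUE)
})

test_that("LOSO folds never see the held-out subject", {
  pat <- make_ground_truth_pattern(80, seed = 7)
  st <- simulate_training_study(6, pattern = pat, seed = 8)
  for (k in c(1, 4, 6)) {
    ref <- loso_fold_model(st, k, alpha = 0.5, lambda = 0.1)
    corrupted <- st
    corrupted$subjects[[k]]$values[] <- 1e6
    corrupted$subjects[[k]]$condition_labels$temperature <-
      rev(corrupted$subjects[[k]]$condition_labels$temperature)
    probe <- loso_fold_model(corrupted, k, alpha = 0.5, lambda = 0.1)
    expect_identical(probe$w_vox, ref$w_vox)
    expect_identical(probe$intercept, ref$intercept)
  }
})

test_that("grid selection finds the minimum and breaks ties toward sparsity", {
  pat <- make_ground_truth_pattern(60, seed = 9)
  st <- simulate_training_study(4, pattern = pat, seed = 9) |>
    suppressWarnings()
  tl <- tune_loso(st, alpha_grid = c(0.5, 1), lambda_grid = c(0.01, 0.1, 1))
  expect_equal(tl$cv_error, min(tl$error_grid))
  # engineered tie: penalties so large that every cell collapses to the
  # intercept-only model -> equal errors -> largest lambda, then largest alpha
  tie <- tune_loso(st, alpha_grid = c(0.5, 1), lambda_grid = c(1e4, 1e5))
  expect_equal(tie$lambda, 1e5)
  expect_equal(tie$alpha, 1)
  expect_error(tune_loso(st, alpha_grid = numeric(0)), "empty")
})

test_that("weight map application yields one estimate per subject and condition", {
  pat <- make_ground_truth_pattern(100, seed = 10)
  st <- simulate_training_study(6, pattern = pat, seed = 10)
  wm <- train_full(st, alpha_grid = 1, lambda_grid = c(0.01, 0.1))
  te <- simulate_test_study(30, pattern = pat, seed = 11)
  mhe <- apply_weight_map(wm, te)
  expect_s3_class(mhe, "mhe_table")
  expect_equal(nrow(mhe), 720)
  expect_true(all(table(mhe$subject) == 24))
  expect_true(all(is.finite(mhe$mhe)))

  # all-zero stack maps to all-zero estimates
  zero <- beta_maps(matrix(0, 24, 100), te$design, "zero")
  expect_true(all(apply_weight_map(wm, zero)$mhe == 0))

  # grid mismatch is an explicit error
  small <- beta_maps(matrix(0, 24, 50), te$design, "small")
  expect_error(apply_weight_map(wm, small), "voxel grid mismatch")
})

test_that("noiseless estimates increase strictly with temperature", {
  pat <- make_ground_truth_pattern(100, seed = 12)
  st <- simulate_training_study(6, pattern = pat, noise_sd = 0.2,
                                subject_sd = 0, seed = 12)
  wm <- train_full(st, alpha_grid = 1, lambda_grid = 0.01)
  te <- simulate_test_study(2, pattern = pat, noise_sd = 0, subject_sd = 0,
                            seed = 13)
  mhe <- apply_weight_map(wm, te)
  for (sub in unique(mhe$subject)) {
    m <- stats::aggregate(mhe ~ temperature, data = mhe[mhe$subject == sub, ],
                          FUN = mean)
    expect_true(all(diff(m$mhe[order(m$temperature)]) > 0))
  }
})
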