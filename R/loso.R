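#' Leave-one-subject-out tuning of the elastic-net decoder
#'
#' For every fold, the by-voxel standardization, the PCA basis, and the
#' elastic-net fit are computed on the n-1 training subjects only; the
#' held-out subject's beta maps are standardized and projected with those
#' fold-internal parameters before prediction, so no information can leak
#' from the held-out subject into the fold model. The grid cell minimizing
#' the mean cross-validated error is selected; exact ties are broken toward
#' sparser models (larger lambda first, then larger alpha).
#'
#' @param study a \code{training_study} (or any list of \code{beta_maps} with
#'   a \code{temperature} label column).
#' @param alpha_grid elastic-net mixing values in (0, 1].
#' @param lambda_grid penalty strengths.
#' @param variance_target PCA retained-variance proportion.
#' @param metric \code{"rmse"} (default) or \code{"mae"}, in degC.
#' @return list of class \code{loso_tuning}: \code{alpha}, \code{lambda},
#'   \code{cv_error} (selected cell), \code{error_grid} (alpha x lambda mean
#'   error), \code{fold_errors} (fold x alpha x lambda), \code{predictions}
#'   (pooled held-out predictions at the selected cell, with \code{subject}
#'   and \code{temperature}), \code{metric}.
#' @export
tune_loso <- function(study,
                      alpha_grid = c(0.1, 0.5, 0.9, 1.0),
                      lambda_grid = 10^seq(-3, 1, length.out = 20),
                      variance_target = 0.999,
                      metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  subjects <- study$subjects
  n_sub <- length(subjects)
  if (n_sub < 3) stop("tune_loso: need >= 3 subjects for LOSO-CV")
  if (!length(alpha_grid) || !length(lambda_grid)) {
    stop("tune_loso: empty tuning grid")
  }
  n_a <- length(alpha_grid)
  n_l <- length(lambda_grid)
  fold_err <- array(NA_real_, c(n_sub, n_a, n_l))
  pred_store <- array(NA_real_,
                      c(n_sub, n_a, n_l,
                        max(vapply(subjects, function(s) nrow(s$values), 1L))))

  for (k in seq_len(n_sub)) {
    train_idx <- setdiff(seq_len(n_sub), k)
    if (length(train_idx) < 2) stop("tune_loso: fold with < 2 training subjects")
    stack <- do.call(rbind, lapply(subjects[train_idx], function(s) s$values))
    ytr <- unlist(lapply(subjects[train_idx],
                         function(s) s$condition_labels$temperature))
    zs <- zscore_voxelwise(stack)
    pca <- fit_pca(zs$z, variance_target)
    z_te <- apply_standardization(subjects[[k]]$values, zs$params)
    s_te <- project_pca(z_te, pca$basis)
    y_te <- subjects[[k]]$condition_labels$temperature
    for (a in seq_len(n_a)) {
      fits <- elastic_net_path(pca$scores, ytr, alpha_grid[a], lambda_grid)
      for (l in seq_len(n_l)) {
        pred <- fits[[l]]$intercept + s_te %*% fits[[l]]$weights
        err <- pred - y_te
        fold_err[k, a, l] <- if (metric == "rmse") {
          sqrt(mean(err^2))
        } else {
          mean(abs(err))
        }
        pred_store[k, a, l, seq_along(pred)] <- pred
      }
    }
  }

  mean_err <- apply(fold_err, c(2, 3), mean)
  best <- min(mean_err)
  cand <- which(mean_err <= best + 1e-12, arr.ind = TRUE)
  # sparser first: larger lambda, then larger alpha
  cand <- cand[order(-lambda_grid[cand[, 2]], -alpha_grid[cand[, 1]]), ,
               drop = FALSE]
  a_sel <- cand[1, 1]
  l_sel <- cand[1, 2]

  preds <- do.call(rbind, lapply(seq_len(n_sub), function(k) {
    y <- subjects[[k]]$condition_labels$temperature
    data.frame(subject = subjects[[k]]$subject_id,
               temperature = y,
               predicted = pred_store[k, a_sel, l_sel, seq_along(y)])
  }))

  structure(list(alpha = alpha_grid[a_sel], lambda = lambda_grid[l_sel],
                 cv_error = mean_err[a_sel, l_sel],
                 error_grid = matrix(mean_err, n_a, n_l,
                                     dimnames = list(alpha = alpha_grid,
                                                     lambda = signif(lambda_grid, 3))),
                 fold_errors = fold_err,
                 predictions = preds,
                 alpha_grid = alpha_grid, lambda_grid = lambda_grid,
                 variance_target = variance_target, metric = metric),
            class = "loso_tuning")
}

#' Fit the model of one leave-one-subject-out fold
#'
#' Standardization, PCA, elastic net, and back-projection computed on all
#' subjects except subject \code{k}, exactly as inside [tune_loso()]. The
#' held-out subject's data are never touched, which makes this the natural
#' probe for leakage diagnostics: any corruption of subject \code{k}'s maps
#' or labels must leave the returned fold model bit-identical.
#'
#' @inheritParams tune_loso
#' @param k index of the held-out subject.
#' @param alpha,lambda elastic-net parameters for the fold fit.
#' @return list with \code{w_vox}, \code{intercept}, \code{weights}
#'   (component space), \code{basis}, \code{standardization}.
#' @export
loso_fold_model <- function(study, k, alpha, lambda,
                            variance_target = 0.999) {
  subjects <- study$subjects
  stopifnot(k >= 1, k <= length(subjects))
  train_idx <- setdiff(seq_along(subjects), k)
  if (length(train_idx) < 2) stop("loso_fold_model: < 2 training subjects")
  stack <- do.call(rbind, lapply(subjects[train_idx], function(s) s$values))
  y <- unlist(lapply(subjects[train_idx],
                     function(s) s$condition_labels$temperature))
  zs <- zscore_voxelwise(stack)
  pca <- fit_pca(zs$z, variance_target)
  fit <- fit_elastic_net(pca$scores, y, alpha, lambda)
  list(w_vox = backproject(fit$weights, pca$basis),
       intercept = fit$intercept,
       weights = fit$weights,
       basis = pca$basis,
       standardization = zs$params)
}

#' Train the full heat-decoding weight map
#'
#' Tunes (alpha, lambda) by leave-one-subject-out cross-validation, then
#' refits standardization, PCA, and the elastic net on all subjects at the
#' selected cell, and back-projects the component weights to voxel space.
#'
#' @inheritParams tune_loso
#' @param tuning optional precomputed \code{loso_tuning} (skips re-tuning).
#' @return object of class \code{heat_weight_map}: \code{w_vox},
#'   \code{intercept}, \code{basis} (\code{pca_basis}),
#'   \code{standardization}, \code{alpha}, \code{lambda}, \code{cv_error},
#'   \code{cv_metric}, \code{n_components}, \code{n_nonzero_components},
#'   \code{loso_predictions}.
#' @examples
#' pat <- make_ground_truth_pattern(150, seed = 5)
#' ts <- simulate_training_study(6, pattern = pat, seed = 5)
#' wm <- train_full(ts, alpha_grid = 1, lambda_grid = c(0.01, 0.1))
#' wm$n_nonzero_components
#' @export
train_full <- function(study,
                       alpha_grid = c(0.1, 0.5, 0.9, 1.0),
                       lambda_grid = 10^seq(-3, 1, length.out = 20),
                       variance_target = 0.999,
                       metric = c("rmse", "mae"),
                       tuning = NULL) {
  metric <- match.arg(metric)
  if (is.null(tuning)) {
    tuning <- tune_loso(study, alpha_grid, lambda_grid, variance_target,
                        metric)
  }
  stack <- do.call(rbind, lapply(study$subjects, function(s) s$values))
  y <- unlist(lapply(study$subjects,
                     function(s) s$condition_labels$temperature))
  zs <- zscore_voxelwise(stack)
  pca <- fit_pca(zs$z, variance_target)
  fit <- fit_elastic_net(pca$scores, y, tuning$alpha, tuning$lambda)
  structure(list(w_vox = backproject(fit$weights, pca$basis),
                 intercept = fit$intercept,
                 component_weights = fit$weights,
                 basis = pca$basis,
                 standardization = zs$params,
                 alpha = tuning$alpha, lambda = tuning$lambda,
                 cv_error = tuning$cv_error, cv_metric = tuning$metric,
                 n_components = ncol(pca$basis$rotation),
                 n_nonzero_components = fit$n_nonzero,
                 loso_predictions = tuning$predictions),
            class = "heat_weight_map")
}

#' @exportS3Method base::print
print.heat_weight_map <- function(x, ...) {
  cat("<heat_weight_map> ", length(x$w_vox), " voxels; ",
      x$n_nonzero_components, "/", x$n_components,
      " nonzero components; alpha = ", x$alpha,
      ", lambda = ", signif(x$lambda, 3),
      "; LOSO ", toupper(x$cv_metric), " = ", signif(x$cv_error, 4),
      " degC\n", sep = "")
  invisible(x)
}

#' Apply a heat weight map to beta maps: the multi-voxel heat estimate
#'
#' The MHE for a condition is the by-voxel dot product of the weight map with
#' the standardized beta map of that condition (no intercept; the intercept
#' shifts all conditions of a subject equally and cancels in within-subject
#' contrasts). By default each subject stack is z-transformed over its own
#' observations (\code{standardize_with = "self"}); alternatively the training
#' standardization parameters stored in the map are applied.
#'
#' @param map a \code{heat_weight_map}.
#' @param betas a \code{beta_maps}, a \code{test_study}, or a list of
#'   \code{beta_maps}.
#' @param standardize_with \code{"self"} or \code{"training"}.
#' @return data.frame of class \code{mhe_table}: one row per subject x
#'   condition with the condition label columns and \code{mhe}.
#' @export
apply_weight_map <- function(map, betas,
                             standardize_with = c("self", "training")) {
  standardize_with <- match.arg(standardize_with)
  stopifnot(inherits(map, "heat_weight_map"))
  blist <- if (inherits(betas, "beta_maps")) {
    list(betas)
  } else if (inherits(betas, "test_study") ||
             inherits(betas, "training_study")) {
    betas$subjects
  } else {
    betas
  }
  out <- lapply(blist, function(b) {
    stopifnot(inherits(b, "beta_maps"))
    if (ncol(b$values) != length(map$w_vox)) {
      stop("apply_weight_map: voxel grid mismatch (map has ",
           length(map$w_vox), " voxels, beta maps have ", ncol(b$values), ")")
    }
    z <- if (standardize_with == "self") {
      zscore_voxelwise(b$values)$z
    } else {
      apply_standardization(b$values, map$standardization)
    }
    mhe <- drop(z %*% map$w_vox)
    data.frame(subject = b$subject_id, b$condition_labels, mhe = mhe)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mhe_table", "data.frame")
  res
}
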