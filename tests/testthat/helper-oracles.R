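# Independent oracles used to verify the package's own implementations.
# Deliberately naive code: plain loops, no shared helpers with R/.

# Elastic-net objective, written out element by element.
oracle_enet_objective <- function(Z, y, w, b0, alpha, lambda) {
  n <- length(y)
  rss <- 0
  for (i in seq_len(n)) {
    pred <- b0
    for (j in seq_len(ncol(Z))) pred <- pred + Z[i, j] * w[j]
    rss <- rss + (y[i] - pred)^2
  }
  pen <- 0
  for (j in seq_len(ncol(Z))) {
    pen <- pen + (1 - alpha) / 2 * w[j]^2 + alpha * abs(w[j])
  }
  rss / (2 * n) + lambda * pen
}

# Naive coordinate descent on centered data, run to tight convergence.
oracle_enet_cd <- function(Z, y, alpha, lambda, tol = 1e-12,
                           max_iter = 50000L) {
  n <- nrow(Z)
  p <- ncol(Z)
  zm <- numeric(p)
  for (j in seq_len(p)) zm[j] <- sum(Z[, j]) / n
  ym <- sum(y) / n
  Zc <- Z
  for (j in seq_len(p)) Zc[, j] <- Z[, j] - zm[j]
  yc <- y - ym
  w <- numeric(p)
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      r_partial <- yc
      for (jj in seq_len(p)) {
        if (jj != j) r_partial <- r_partial - Zc[, jj] * w[jj]
      }
      rho <- sum(Zc[, j] * r_partial) / n
      vj <- sum(Zc[, j]^2) / n
      num <- sign(rho) * max(abs(rho) - lambda * alpha, 0)
      w_new <- num / (vj + lambda * (1 - alpha))
      delta <- max(delta, abs(w_new - w[j]))
      w[j] <- w_new
    }
    if (delta < tol) break
  }
  b0 <- ym
  for (j in seq_len(p)) b0 <- b0 - zm[j] * w[j]
  list(weights = w, intercept = b0)
}

# Tiny hand-built trial sequence with explicit onsets, for regressor tests.
make_toy_sequence <- function(plateau_onsets, temperature = 47.1,
                              picture = "neutral", plateau_duration = 14,
                              session_duration = NULL) {
  n <- length(plateau_onsets)
  trials <- data.frame(
    temperature = rep(temperature, n),
    picture = rep(picture, n),
    cue_onset = pmax(plateau_onsets - 2, 0),
    plateau_onset = plateau_onsets,
    plateau_duration = plateau_duration,
    rating_onset = plateau_onsets + plateau_duration + 4,
    rating_duration = 7.5)
  structure(list(trials = trials,
                 session_duration = session_duration %||%
                   (max(plateau_onsets) + plateau_duration + 30),
                 max_run = Inf, seed = NA_integer_),
            class = "trial_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal weight map wrapper around a raw voxel weight vector.
make_identity_weight_map <- function(w_vox) {
  structure(list(w_vox = w_vox, intercept = 0,
                 component_weights = w_vox,
                 basis = NULL, standardization = NULL,
                 alpha = 1, lambda = 0, cv_error = NA_real_,
                 cv_metric = "rmse",
                 n_components = length(w_vox),
                 n_nonzero_components = sum(w_vox != 0),
                 loso_predictions = NULL),
            class = "heat_weight_map")
}
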