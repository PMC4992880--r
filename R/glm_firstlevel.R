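#' Discrete-cosine high-pass basis
#'
#' The set of low-frequency discrete cosine transform regressors whose periods
#' exceed \code{cutoff} seconds; including them as nuisance columns in the GLM
#' removes slow scanner drift, equivalent (for the condition betas) to
#' applying the residual-forming high-pass filter. The number of columns is
#' \code{floor(2 * n_scans * tr / cutoff)}; the constant term is not part of
#' the basis.
#'
#' @param n_scans number of volumes (>= 2).
#' @param tr repetition time in seconds.
#' @param cutoff filter width in seconds (default 400); must exceed
#'   \code{2 * tr}.
#' @return matrix with \code{n_scans} rows and \code{k} zero-mean, unit-norm
#'   columns (possibly zero columns for very large cutoffs).
#' @examples
#' ncol(dct_highpass_basis(700, 2))   # floor(2800/400) = 7
#' @export
dct_highpass_basis <- function(n_scans, tr, cutoff = 400) {
  stopifnot(n_scans >= 2, tr > 0)
  if (is.finite(cutoff) && cutoff <= 2 * tr) {
    stop("dct_highpass_basis: cutoff must exceed 2*tr for any filtering")
  }
  k <- if (is.finite(cutoff)) floor(2 * n_scans * tr / cutoff) else 0L
  k <- min(k, n_scans - 1L)
  if (k < 1L) {
    return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  }
  t <- seq_len(n_scans) - 0.5
  X <- vapply(seq_len(k), function(r) {
    cos(pi * r * t / n_scans)
  }, numeric(n_scans))
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  colnames(X) <- paste0("dct", seq_len(k))
  X
}

#' Build the first-level design matrix for a simulated run
#'
#' One HRF-convolved boxcar column per experimental condition (the 14 s heat
#' plateau shifted by \code{delay} seconds), plus nuisance columns: a
#' convolved boxcar over all rating periods, the six head-motion parameters,
#' the discrete-cosine high-pass set, and a constant.
#'
#' @param run a \code{bold_run}.
#' @param delay,duration boxcar shift and length in seconds.
#' @param hp_cutoff high-pass width in seconds (\code{Inf} disables).
#' @param include_motion,include_rating toggle the nuisance blocks.
#' @return object of class \code{design_matrix}: list with \code{matrix},
#'   \code{names}, \code{condition_columns}, \code{nuisance_columns}.
#' @export
build_design_matrix <- function(run, delay = 5, duration = 14,
                                hp_cutoff = 400,
                                include_motion = TRUE,
                                include_rating = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  n_vol <- nrow(run$data)
  labels <- run$condition_labels

  Xc <- vapply(labels, function(cc) {
    convolved_regressor(run$seq, cc, tr_s = run$tr_s, n_vol = n_vol,
                        delay = delay, duration = duration)
  }, numeric(n_vol))
  colnames(Xc) <- labels

  nuis <- list()
  if (include_rating) {
    tr <- run$seq$trials
    # a single regressor covering every rating period, convolved like the
    # condition boxcars but with zero delay
    rate_seq <- run$seq
    rate_seq$trials$plateau_onset <- tr$rating_onset
    nuis$rating <- convolved_regressor(
      rate_seq, rep(TRUE, nrow(tr)), tr_s = run$tr_s, n_vol = n_vol,
      delay = 0, duration = tr$rating_duration[1])
  }
  if (include_motion) {
    M <- run$motion_params[seq_len(n_vol), , drop = FALSE]
    colnames(M) <- paste0("motion", 1:6)
    nuis$motion <- M
  }
  D <- dct_highpass_basis(n_vol, run$tr_s, hp_cutoff)
  X <- cbind(Xc,
             if (length(nuis)) do.call(cbind, nuis),
             D,
             constant = 1)
  nm <- colnames(X)
  structure(list(matrix = X, names = nm,
                 condition_columns = seq_along(labels),
                 nuisance_columns = seq.int(length(labels) + 1L, ncol(X))),
            class = "design_matrix")
}

#' Pooled lag-1 autocorrelation of residuals
#'
#' Single AR(1) coefficient pooled over all in-mask voxels: the ratio of the
#' summed lag-1 cross-products to the summed squares of the (column-demeaned)
#' residuals, clipped to (-0.99, 0.99).
#'
#' @param residuals time x voxel matrix (>= 3 rows).
#' @param mask logical/integer voxel selector (default: all).
#' @return scalar rho.
#' @export
estimate_ar1 <- function(residuals, mask = NULL) {
  stopifnot(nrow(residuals) >= 3)
  E <- if (is.null(mask)) residuals else residuals[, mask, drop = FALSE]
  E <- scale(E, center = TRUE, scale = FALSE)
  denom <- sum(E^2)
  if (denom <= .Machine$double.eps * length(E)) {
    warning("estimate_ar1: zero-variance residuals; returning rho = 0")
    return(0)
  }
  n <- nrow(E)
  num <- sum(E[-1, , drop = FALSE] * E[-n, , drop = FALSE])
  max(-0.99, min(0.99, num / denom))
}

#' AR(1) prewhitening transform
#'
#' Applies the whitening filter for an AR(1) process to both sides of the
#' model: the first row is scaled by \code{sqrt(1 - rho^2)} and each later row
#' becomes \code{x_t - rho * x_{t-1}}. Generalized least squares via
#' prewhitened ordinary least squares.
#'
#' @param Y time x voxel data matrix.
#' @param X time x regressor matrix (or a \code{design_matrix}).
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @return list with \code{Y} and \code{X} transformed.
#' @export
prewhiten <- function(Y, X, rho) {
  stopifnot(abs(rho) < 1)
  if (inherits(X, "design_matrix")) X <- X$matrix
  if (rho == 0) return(list(Y = Y, X = X))
  W <- function(M) {
    M2 <- M
    M2[1, ] <- sqrt(1 - rho^2) * M[1, ]
    M2[-1, ] <- M[-1, , drop = FALSE] -
      rho * M[-nrow(M), , drop = FALSE]
    M2
  }
  list(Y = W(as.matrix(Y)), X = W(as.matrix(X)))
}

#' Fit the first-level GLM for one run
#'
#' Two-pass estimation: ordinary least squares, pooled AR(1) estimation from
#' the residuals, then prewhitened least squares. Condition betas are
#' extracted by label into a [beta_maps()] object; per-voxel residual variance
#' and the pooled rho are attached.
#'
#' @param run a \code{bold_run}.
#' @param X a \code{design_matrix} (default: [build_design_matrix()] on the
#'   run).
#' @param two_pass_ar1 if FALSE, stop after the OLS pass.
#' @param subject_id identifier stored in the result.
#' @return \code{beta_maps} with extra fields \code{residual_variance},
#'   \code{rho}, \code{design_names}, and a \code{condition} label column.
#' @export
fit_glm <- function(run, X = build_design_matrix(run), two_pass_ar1 = TRUE,
                    subject_id = "subject") {
  stopifnot(inherits(run, "bold_run"), inherits(X, "design_matrix"))
  Y <- run$data
  M <- X$matrix
  stopifnot(nrow(M) == nrow(Y))
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    bad <- colnames(M)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(M))]]
    stop("fit_glm: design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  rho <- 0
  if (two_pass_ar1) {
    E <- Y - M %*% B
    rho <- estimate_ar1(E, run$mask)
    pw <- prewhiten(Y, M, rho)
    qrW <- qr(pw$X)
    B <- qr.coef(qrW, pw$Y)
    E <- pw$Y - pw$X %*% B
  } else {
    E <- Y - M %*% B
  }
  dof <- nrow(M) - ncol(M)
  resvar <- colSums(E^2) / dof

  ci <- X$condition_columns
  out <- beta_maps(values = B[ci, , drop = FALSE],
                   condition_labels = data.frame(condition = X$names[ci]),
                   subject_id = subject_id,
                   mask = run$mask)
  out$residual_variance <- resvar
  out$rho <- rho
  out$design_names <- X$names
  out
}
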