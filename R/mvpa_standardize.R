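#' By-voxel z-transform of a beta-map stack
#'
#' Standardizes each voxel column of an observation x voxel stack to mean 0
#' and sample SD 1. Voxels with zero variance are set to 0 and recorded, so
#' they can never influence the decoder.
#'
#' @param stack observation x voxel matrix (>= 2 rows).
#' @return list with \code{z} (standardized stack) and \code{params}
#'   (class \code{standardization_params}: \code{mean}, \code{sd},
#'   \code{zero_variance} index vector).
#' @examples
#' zscore_voxelwise(cbind(a = 1:3, b = c(5, 5, 5)))$z
#' @export
zscore_voxelwise <- function(stack) {
  stack <- as.matrix(stack)
  if (nrow(stack) < 2) {
    stop("zscore_voxelwise: need >= 2 observations to standardize")
  }
  mu <- colMeans(stack)
  sd <- apply(stack, 2, stats::sd)
  zero <- which(!is.finite(sd) | sd < 1e-12)
  sd_safe <- sd
  sd_safe[zero] <- 1
  z <- sweep(sweep(stack, 2, mu, "-"), 2, sd_safe, "/")
  if (length(zero)) z[, zero] <- 0
  params <- structure(list(mean = mu, sd = sd, zero_variance = zero),
                      class = "standardization_params")
  list(z = z, params = params)
}

#' Apply stored standardization parameters to a new stack
#'
#' @param stack observation x voxel matrix on the same voxel grid.
#' @param params a \code{standardization_params} object.
#' @return standardized matrix; zero-variance training voxels are set to 0.
#' @export
apply_standardization <- function(stack, params) {
  stack <- as.matrix(stack)
  stopifnot(inherits(params, "standardization_params"),
            ncol(stack) == length(params$mean))
  sd_safe <- params$sd
  sd_safe[params$zero_variance] <- 1
  z <- sweep(sweep(stack, 2, params$mean, "-"), 2, sd_safe, "/")
  if (length(params$zero_variance)) z[, params$zero_variance] <- 0
  z
}

#' Principal-component reduction of a z-stack
#'
#' Removes the per-voxel feature mean and keeps the smallest number of
#' principal components whose cumulative variance share reaches
#' \code{variance_target} (capped at \code{min(n_obs - 1, n_voxels)}).
#'
#' @param z observation x voxel matrix.
#' @param variance_target retained-variance proportion in (0, 1]; default
#'   0.999.
#' @return list with \code{basis} (class \code{pca_basis}: \code{rotation}
#'   voxel x component, \code{center}, \code{variance_shares},
#'   \code{variance_target}) and \code{scores} (observation x component).
#' @export
fit_pca <- function(z, variance_target = 0.999) {
  z <- as.matrix(z)
  if (nrow(z) < 2 || ncol(z) < 1) stop("fit_pca: empty or single-row stack")
  if (variance_target <= 0 || variance_target > 1) {
    stop("fit_pca: variance_target must be in (0, 1]")
  }
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > .Machine$double.eps * ev[1]]
  shares <- ev / sum(pc$sdev^2)
  cum <- cumsum(shares)
  k <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  k <- min(k, nrow(z) - 1L, ncol(z))
  basis <- structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                          center = pc$center,
                          variance_shares = shares[seq_len(k)],
                          variance_target = variance_target),
                     class = "pca_basis")
  list(basis = basis, scores = pc$x[, seq_len(k), drop = FALSE])
}

#' Project a stack onto a fitted PCA basis
#'
#' @param stack observation x voxel matrix.
#' @param basis a \code{pca_basis}.
#' @return observation x component score matrix.
#' @export
project_pca <- function(stack, basis) {
  stopifnot(inherits(basis, "pca_basis"),
            ncol(stack) == nrow(basis$rotation))
  sweep(as.matrix(stack), 2, basis$center, "-") %*% basis$rotation
}

#' Back-project component weights to voxel space
#'
#' Maps elastic-net weights estimated on principal-component scores back to a
#' voxel weight vector via the PCA loading matrix:
#' \code{w_vox = rotation \%*\% w_comp}. The voxel-space prediction
#' \code{b0 + (x - center) . w_vox} is then identical to the component-space
#' prediction for any map \code{x}.
#'
#' @param component_weights numeric vector, one weight per retained component.
#' @param basis a \code{pca_basis}.
#' @return numeric voxel weight vector.
#' @export
backproject <- function(component_weights, basis) {
  stopifnot(inherits(basis, "pca_basis"),
            length(component_weights) == ncol(basis$rotation))
  drop(basis$rotation %*% component_weights)
}
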