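#' Elastic-net regression by cyclic coordinate descent
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - z_i^\top w)^2 +
#'   \lambda\left[\frac{1-\alpha}{2}\|w\|_2^2 + \alpha\|w\|_1\right]}
#' over the component weights \code{w} and the unpenalized intercept
#' \code{b0}, by soft-thresholded cyclic coordinate descent on the raw
#' (unstandardized) predictor columns. \code{alpha = 1} is the lasso;
#' \code{alpha = 0} (pure ridge) is outside the lasso family used here and is
#' rejected — use a small positive \code{alpha} instead.
#'
#' @param Z observation x predictor matrix (typically PCA scores).
#' @param y numeric response (degC temperature targets).
#' @param alpha mixing parameter in (0, 1].
#' @param lambda penalty strength (>= 0).
#' @param w_init optional warm-start weight vector.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter iteration budget.
#' @return list with \code{weights}, \code{intercept}, \code{objective},
#'   \code{n_nonzero}, \code{iterations}, \code{converged}.
#' @examples
#' Z <- matrix(rnorm(80), 20, 4); y <- Z %*% c(1, 0, -1, 0) + rnorm(20, sd = .1)
#' fit_elastic_net(Z, y, alpha = 1, lambda = 0.1)$n_nonzero
#' @export
fit_elastic_net <- function(Z, y, alpha, lambda, w_init = NULL,
                            tol = 1e-10, max_iter = 10000L) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  stopifnot(nrow(Z) == length(y), lambda >= 0)
  if (alpha <= 0 || alpha > 1) {
    stop("fit_elastic_net: alpha must be in (0, 1]; pure ridge (alpha = 0) ",
         "is outside the lasso family — use a small positive alpha instead")
  }
  n <- nrow(Z)
  p <- ncol(Z)
  w <- if (is.null(w_init)) numeric(p) else {
    stopifnot(length(w_init) == p)
    as.numeric(w_init)
  }
  zbar <- colMeans(Z)
  ybar <- mean(y)
  Zc <- sweep(Z, 2, zbar, "-")
  yc <- y - ybar
  v <- colMeans(Zc^2)                     # per-column curvature
  r <- yc - Zc %*% w                      # residual at current w
  soft <- function(x, g) sign(x) * max(abs(x) - g, 0)
  denom <- v + lambda * (1 - alpha)
  thr <- lambda * alpha
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (v[j] == 0) next
      wj_old <- w[j]
      rho <- mean(Zc[, j] * r) + v[j] * wj_old
      wj_new <- soft(rho, thr) / denom[j]
      if (wj_new != wj_old) {
        r <- r - Zc[, j] * (wj_new - wj_old)
        w[j] <- wj_new
        delta <- max(delta, abs(wj_new - wj_old))
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  b0 <- ybar - sum(zbar * w)
  list(weights = w, intercept = b0,
       objective = elastic_net_objective(Z, y, w, b0, alpha, lambda),
       n_nonzero = sum(w != 0), iterations = it, converged = converged)
}

#' Elastic-net objective value
#'
#' @param Z,y data; \code{w},\code{b0} coefficients; \code{alpha},\code{lambda}
#'   penalty parameters.
#' @return scalar objective.
#' @export
elastic_net_objective <- function(Z, y, w, b0, alpha, lambda) {
  r <- y - b0 - as.matrix(Z) %*% w
  sum(r^2) / (2 * length(y)) +
    lambda * ((1 - alpha) / 2 * sum(w^2) + alpha * sum(abs(w)))
}

# Fit a decreasing lambda path with warm starts; returns a list of fits.
elastic_net_path <- function(Z, y, alpha, lambdas, tol = 1e-10) {
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  w <- NULL
  for (i in ord) {
    f <- fit_elastic_net(Z, y, alpha, lambdas[i], w_init = w, tol = tol)
    fits[[i]] <- f
    w <- f$weights
  }
  fits
}
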