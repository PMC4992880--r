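#' Create a ground-truth multivoxel temperature-coding pattern
#'
#' The simulated analogue of the trained heat weight map: a sparse vector of
#' per-voxel slopes (signal units per degC) over a voxel grid. A random subset
#' of voxels is "active" with Gaussian weights of scale \code{effect_scale};
#' all other weights are exactly zero. Used to plant a linear temperature code
#' in simulated beta maps and BOLD runs, and as the reference in
#' parameter-recovery checks.
#'
#' @param n_voxels integer, number of voxels on the grid.
#' @param active_fraction proportion of voxels carrying signal (0, 1].
#' @param effect_scale standard deviation of active-voxel weights, in signal
#'   units per degC.
#' @param baseline_amplitude constant signal offset shared by all voxels.
#' @param seed integer seed.
#' @return An object of class \code{ground_truth_pattern}: list with
#'   \code{weights} (length \code{n_voxels}), \code{active} (integer indices),
#'   \code{baseline_amplitude}, \code{seed}.
#' @examples
#' pat <- make_ground_truth_pattern(1000, active_fraction = 0.1, seed = 7)
#' sum(pat$weights != 0)   # 100
#' @export
make_ground_truth_pattern <- function(n_voxels,
                                      active_fraction = 0.1,
                                      effect_scale = 0.2,
                                      baseline_amplitude = 100,
                                      seed = 1L) {
  if (n_voxels < 1L) stop("make_ground_truth_pattern: n_voxels must be >= 1")
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("make_ground_truth_pattern: active_fraction must be in (0, 1]")
  }
  local_rng(seed)
  n_active <- max(1L, round(n_voxels * active_fraction))
  active <- sort(sample.int(n_voxels, n_active))
  weights <- numeric(n_voxels)
  weights[active] <- stats::rnorm(n_active, mean = 0, sd = 1) * effect_scale
  out <- list(weights = weights, active = active,
              baseline_amplitude = baseline_amplitude,
              effect_scale = effect_scale, seed = seed)
  class(out) <- "ground_truth_pattern"
  out
}

#' @exportS3Method base::print
print.ground_truth_pattern <- function(x, ...) {
  cat("<ground_truth_pattern> ", length(x$weights), " voxels, ",
      length(x$active), " active, effect scale ", x$effect_scale,
      " signal/degC\n", sep = "")
  invisible(x)
}
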