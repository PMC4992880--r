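#' Simulate one BOLD run for a trial sequence
#'
#' Generates a time-by-voxel signal matrix for a session: for every
#' experimental condition the HRF-convolved plateau boxcar enters each voxel
#' with amplitude \code{condition_amplitudes[condition] + temperature *
#' pattern$weights[voxel]}, on top of the pattern's baseline and additive
#' AR(1) noise. Acquisition mirrors the scanner protocol: volumes every
#' \code{tr_s} seconds, with \code{n_discard} initial dummy volumes acquired
#' but dropped (T1 saturation), so the returned matrix holds
#' \code{ceiling(session_duration / tr_s)} retained rows.
#'
#' @param seq a \code{trial_sequence}.
#' @param pattern a \code{ground_truth_pattern}.
#' @param condition_amplitudes named numeric vector of per-condition signal
#'   amplitudes keyed by \code{"temperature|picture"} labels; unnamed scalar =
#'   shared amplitude; missing conditions get 0.
#' @param noise_sd innovation SD of the AR(1) noise (>= 0).
#' @param ar1_rho lag-1 autocorrelation of the noise, |rho| < 1.
#' @param tr_s repetition time in seconds.
#' @param n_discard dummy volumes acquired before the session start.
#' @param delay,duration boxcar shift and length (s), matching the first-level
#'   model.
#' @param motion_sd innovation SD of the 6 simulated head-motion parameter
#'   random walks (nuisance columns only; motion never enters the signal).
#' @param seed integer seed.
#' @return Object of class \code{bold_run}: list with \code{data} (time x
#'   voxel), \code{tr_s}, \code{n_discard}, \code{n_acquired},
#'   \code{motion_params} (time x 6), \code{mask} (logical), \code{seq},
#'   \code{condition_labels}, and the true amplitude matrix
#'   \code{amplitudes} (condition x voxel) for recovery checks.
#' @examples
#' seqs <- generate_trial_sequence(seed = 2)
#' pat <- make_ground_truth_pattern(50, seed = 2)
#' run <- simulate_bold_run(seqs, pat, noise_sd = 0.5, seed = 2)
#' dim(run$data)
#' @export
simulate_bold_run <- function(seq, pattern,
                              condition_amplitudes = 0,
                              noise_sd = 1,
                              ar1_rho = 0.3,
                              tr_s = 2,
                              n_discard = 5L,
                              delay = 5,
                              duration = 14,
                              motion_sd = 0.02,
                              seed = 1L) {
  stopifnot(inherits(seq, "trial_sequence"),
            inherits(pattern, "ground_truth_pattern"),
            noise_sd >= 0, abs(ar1_rho) < 1, tr_s > 0)
  local_rng(seed)

  n_vol <- ceiling(seq$session_duration / tr_s)
  n_vox <- length(pattern$weights)
  labels <- sort(unique(trial_condition_labels(seq)))
  temps <- as.numeric(sub("\\|.*$", "", labels))

  amp_cond <- if (is.null(names(condition_amplitudes))) {
    stats::setNames(rep(condition_amplitudes[1], length(labels)), labels)
  } else {
    a <- stats::setNames(numeric(length(labels)), labels)
    hit <- intersect(names(condition_amplitudes), labels)
    a[hit] <- condition_amplitudes[hit]
    a
  }

  # condition x voxel amplitude matrix: shared condition amplitude plus the
  # temperature-scaled multivoxel pattern
  A <- outer(amp_cond, rep(1, n_vox)) + outer(temps, pattern$weights)

  X <- vapply(labels, function(cc) {
    convolved_regressor(seq, cc, tr_s = tr_s, n_vol = n_vol,
                        delay = delay, duration = duration)
  }, numeric(n_vol))

  signal <- X %*% A + pattern$baseline_amplitude

  noise <- matrix(0, n_vol, n_vox)
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_vol * n_vox, sd = noise_sd), n_vol, n_vox)
    noise <- eps
    if (ar1_rho != 0) {
      noise[1, ] <- eps[1, ] / sqrt(1 - ar1_rho^2)
      for (t in 2:n_vol) noise[t, ] <- ar1_rho * noise[t - 1, ] + eps[t, ]
    }
  }

  motion <- apply(matrix(stats::rnorm(n_vol * 6, sd = motion_sd), n_vol, 6),
                  2, cumsum)

  out <- list(data = signal + noise,
              tr_s = tr_s,
              n_discard = as.integer(n_discard),
              n_acquired = n_vol + as.integer(n_discard),
              motion_params = motion,
              mask = rep(TRUE, n_vox),
              seq = seq,
              condition_labels = labels,
              amplitudes = A,
              ar1_rho = ar1_rho,
              seed = seed)
  class(out) <- "bold_run"
  out
}

#' @exportS3Method base::print
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", nrow(x$data), " retained volumes (",
      x$n_acquired, " acquired, TR ", x$tr_s, " s), ",
      ncol(x$data), " voxels, ", length(x$condition_labels),
      " conditions\n", sep = "")
  invisible(x)
}
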