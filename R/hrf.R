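#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF — a response gamma density minus a scaled
#' undershoot gamma density — on a regular grid covering \code{duration}
#' seconds. With the default parameters (response delay 6 s, undershoot delay
#' 16 s, both dispersions 1 s, undershoot ratio 1/6) the curve peaks close to
#' 5 s. The kernel is scaled to peak amplitude 1, so that a convolved boxcar
#' plateaus at the stimulus amplitude and GLM betas read directly in signal
#' units.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param peak_delay,undershoot_delay gamma shape-controlling delays (s).
#' @param peak_disp,undershoot_disp gamma dispersions (s); must be positive.
#' @param undershoot_ratio response/undershoot amplitude ratio.
#' @param duration kernel support in seconds.
#' @return numeric vector of kernel values at \code{seq(0, duration, by = dt)}.
#' @examples
#' h <- canonical_hrf(dt = 0.1)
#' h[1]                                   # 0 at t = 0
#' (which.max(h) - 1) * 0.1               # peak near 5 s
#' @export
canonical_hrf <- function(dt,
                          peak_delay = 6,
                          undershoot_delay = 16,
                          peak_disp = 1,
                          undershoot_disp = 1,
                          undershoot_ratio = 6,
                          duration = 32) {
  if (dt <= 0) stop("canonical_hrf: dt must be > 0")
  if (peak_disp <= 0 || undershoot_disp <= 0) {
    stop("canonical_hrf: dispersion parameters must be positive")
  }
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / undershoot_ratio
  h / max(h)
}

#' Boxcar indicator time course for one condition
#'
#' For every trial of \code{seq} matching \code{condition}, the regressor is 1
#' on the interval \code{[plateau_onset + delay, plateau_onset + delay +
#' duration)} and 0 elsewhere; the 5 s default delay absorbs the onset latency
#' of thermode heat perception. Sampling uses the left-edge convention: grid
#' point t is "on" iff t lies inside the half-open interval.
#'
#' @param seq a \code{trial_sequence}.
#' @param condition either a character condition label (matched against
#'   \code{paste(temperature, picture)}) or a logical/integer trial selector.
#' @param delay onset shift in seconds (>= 0).
#' @param duration "on" duration in seconds.
#' @param dt sampling interval in seconds.
#' @param n_samples optional; number of grid points (defaults to covering the
#'   session).
#' @return numeric 0/1 vector sampled at \code{(0, dt, 2 dt, ...)}.
#' @export
build_boxcar <- function(seq, condition, delay = 5, duration = 14, dt,
                         n_samples = NULL) {
  stopifnot(inherits(seq, "trial_sequence"), delay >= 0, dt > 0)
  tr <- seq$trials
  idx <- if (is.character(condition)) {
    which(trial_condition_labels(seq) == condition)
  } else {
    which(rep_len(TRUE, nrow(tr)) & condition)
  }
  if (is.null(n_samples)) n_samples <- ceiling(seq$session_duration / dt)
  times <- (seq_len(n_samples) - 1) * dt
  x <- numeric(n_samples)
  grid_end <- times[n_samples] + dt
  for (i in idx) {
    on <- tr$plateau_onset[i] + delay
    off <- on + duration
    if (off > grid_end) {
      warning("build_boxcar: shifted interval [", round(on, 1), ", ",
              round(off, 1), ") for trial ", i,
              " extends past the sampled session; truncated")
    }
    x[times >= on & times < off] <- 1
  }
  x
}

# "temperature|picture" label per trial, the condition key used throughout.
trial_condition_labels <- function(seq) {
  paste(format(seq$trials$temperature, nsmall = 1, trim = TRUE),
        seq$trials$picture, sep = "|")
}

# Convolve a fine-grid stimulus course with the HRF and sample at volume
# onsets (times 0, TR, 2 TR, ...). Shared by the simulator and the design
# matrix builder so that planted and modelled regressors are identical.
convolved_regressor <- function(seq, condition, tr_s, n_vol,
                                delay = 5, duration = 14,
                                oversample = 16L, hrf_params = list()) {
  dt <- tr_s / oversample
  n_fine <- ceiling((n_vol * tr_s + 40) / dt)   # pad for kernel tail
  box <- build_boxcar(seq, condition, delay = delay, duration = duration,
                      dt = dt, n_samples = n_fine)
  h <- do.call(canonical_hrf, c(list(dt = dt), hrf_params))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt
  conv <- conv / sum(h * dt)   # plateau of a long boxcar = 1
  idx <- 1L + (seq_len(n_vol) - 1L) * oversample
  conv[idx]
}
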