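#' Generate a pseudo-randomized factorial trial sequence
#'
#' Builds the timing backbone of one scanning session of the thermo-visual
#' block design: every combination of thermode temperature and picture
#' condition occurs exactly \code{reps} times, and the order is
#' pseudo-randomized so that no more than \code{max_run} consecutive trials
#' share a temperature or a picture condition (the operational definition of
#' "avoid clustering").
#'
#' Each trial consists of a 1 s visual cue, a 0.5 s fixation, a temperature
#' ramp (10 degC/s from the 35 degC baseline), a 14 s plateau during which the
#' pictures are shown, a ramp-down, a rest interval drawn uniformly from
#' \code{gap_range}, a rating period, and a closing fixation interval drawn
#' from \code{gap_range}.
#'
#' @param temperatures numeric vector of plateau temperatures in degC.
#' @param picture_conditions character vector of picture condition labels.
#' @param reps integer, repetitions of each (temperature, picture) cell.
#' @param max_run integer, longest admissible run of trials sharing a
#'   temperature or picture label.
#' @param gap_range length-2 numeric, uniform range (s) for the rest and
#'   inter-trial fixation intervals.
#' @param rating_duration numeric, duration (s) of the rating activity used
#'   for the nuisance regressor; the default is the mean observed response
#'   time of 7.5 s.
#' @param rating_window numeric, fixed response window (s) the session
#'   reserves per trial regardless of how fast the ratings are submitted
#'   (14 s by design, so participants cannot shorten the session).
#' @param plateau_duration numeric, plateau length in s (14 by design).
#' @param baseline_temp numeric, thermode baseline in degC; ramp times are
#'   computed from \code{abs(temperature - baseline_temp)} at 10 degC/s.
#' @param max_tries integer, rejection-sampling budget before giving up.
#' @param seed integer seed; identical seeds give identical sequences.
#'
#' @return An object of class \code{trial_sequence}: a list with \code{trials}
#'   (a data.frame with columns \code{temperature}, \code{picture},
#'   \code{cue_onset}, \code{plateau_onset}, \code{plateau_duration},
#'   \code{rating_onset}, \code{rating_duration}) and \code{session_duration}
#'   in seconds.
#' @examples
#' seq36 <- generate_trial_sequence(seed = 1)
#' nrow(seq36$trials)            # 36
#' table(seq36$trials$temperature, seq36$trials$picture)
#' @export
generate_trial_sequence <- function(temperatures = c(35.0, 44.7, 47.1),
                                    picture_conditions = c("negative", "neutral",
                                                           "positive", "scrambled"),
                                    reps = 3L,
                                    max_run = 2L,
                                    gap_range = c(3, 6),
                                    rating_duration = 7.5,
                                    rating_window = 14,
                                    plateau_duration = 14,
                                    baseline_temp = 35.0,
                                    max_tries = 5000L,
                                    seed = 1L) {
  stopifnot(reps >= 1L, max_run >= 1L, length(gap_range) == 2L,
            gap_range[1] <= gap_range[2], plateau_duration > 0)
  cells <- expand.grid(temperature = temperatures,
                       picture = picture_conditions,
                       stringsAsFactors = FALSE)
  pool <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
  n_trials <- nrow(pool)

  longest_run <- function(x) max(rle(as.character(x))$lengths)

  order_ok <- function(ord) {
    tt <- pool$temperature[ord]
    pp <- pool$picture[ord]
    (length(unique(tt)) == 1L || longest_run(tt) <= max_run) &&
      (length(unique(pp)) == 1L || longest_run(pp) <= max_run)
  }

  rng <- local_rng(seed)
  ord <- NULL
  for (i in seq_len(max_tries)) {
    cand <- sample.int(n_trials)
    if (order_ok(cand)) { ord <- cand; break }
  }
  if (is.null(ord)) {
    stop("generate_trial_sequence: no ordering with max_run = ", max_run,
         " found within ", max_tries, " tries; the run-length constraint ",
         "appears infeasible for this design")
  }
  trials <- pool[ord, , drop = FALSE]
  rownames(trials) <- NULL

  ramp_up <- abs(trials$temperature - baseline_temp) / 10
  rest_gap <- stats::runif(n_trials, gap_range[1], gap_range[2])
  iti_gap <- stats::runif(n_trials, gap_range[1], gap_range[2])

  cue_onset <- numeric(n_trials)
  plateau_onset <- numeric(n_trials)
  rating_onset <- numeric(n_trials)
  t <- 0
  for (i in seq_len(n_trials)) {
    cue_onset[i] <- t
    t <- t + 1 + 0.5                       # cue + fixation
    t <- t + ramp_up[i]
    plateau_onset[i] <- t
    t <- t + plateau_duration
    t <- t + ramp_up[i]                    # ramp-down, same rate
    t <- t + rest_gap[i]
    rating_onset[i] <- t
    t <- t + rating_window
    t <- t + iti_gap[i]
  }

  out <- list(
    trials = data.frame(trials,
                        cue_onset = cue_onset,
                        plateau_onset = plateau_onset,
                        plateau_duration = plateau_duration,
                        rating_onset = rating_onset,
                        rating_duration = rating_duration),
    session_duration = t,
    max_run = max_run,
    seed = seed
  )
  class(out) <- "trial_sequence"
  out
}

#' @exportS3Method base::print
print.trial_sequence <- function(x, ...) {
  cat("<trial_sequence> ", nrow(x$trials), " trials, ",
      sprintf("%.1f", x$session_duration / 60), " min\n", sep = "")
  print(utils::head(x$trials, 4))
  invisible(x)
}

# Restore the caller's RNG state on exit; all generators route their
# randomness through this so they are pure functions of (config, seed).
local_rng <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}
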