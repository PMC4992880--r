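#' Effect structure for the rating generator
#'
#' Bundles the planted fixed-effect structure for one visual-analogue-scale
#' (VAS, 0-100) outcome. The shipped defaults reproduce the marginal effect
#' structure of the study the package emulates: intensity ratings rise by
#' 47.8 VAS from non-noxious (44.7 degC) to noxious (47.1 degC) heat and
#' unpleasantness by 50.1 VAS; negative pictures raise ratings slightly
#' relative to neutral and positive; oxytocin raises intensity at non-noxious
#' heat (+3.54) and lowers it at noxious heat (-2.38); and for unpleasantness
#' the negative-minus-positive contrast at noxious heat widens under oxytocin
#' (7.08 VAS) relative to placebo (3.26 VAS).
#'
#' @param measure \code{"intensity"} or \code{"unpleasantness"}; selects the
#'   default fixed-effect values.
#' @param grand_mean mean VAS across the non-noxious/noxious cells.
#' @param temp_effect noxious minus non-noxious difference (VAS).
#' @param valence_effects named offsets (VAS) for
#'   negative/neutral/positive/scrambled.
#' @param oxytocin_by_temp named length-2 vector: oxytocin-minus-placebo
#'   effect (VAS) at \code{non_noxious} and \code{noxious} heat.
#' @param threeway_neg_vs_pos_oxt_noxious,threeway_neg_vs_pos_placebo_noxious
#'   planted negative-minus-positive difference (VAS) at noxious heat under
#'   each medication; values equal to
#'   \code{valence_effects["negative"] - valence_effects["positive"]} plant no
#'   three-way interaction.
#' @param baseline_mean mean VAS at the 35.0 degC control temperature.
#' @param sd_subject_intercept,sd_subject_slope SDs of the by-subject random
#'   intercept and random noxious-heat slope (VAS).
#' @param sd_residual trial-level residual SD (VAS).
#' @param pain_midpoint,pain_scale logistic psychometric function for the
#'   binary pain judgment: P(painful) = plogis((T - midpoint)/scale). The
#'   defaults are obtained by passing the study's printed painful proportions
#'   at 44.7 degC (3.1%) and 47.1 degC (83.6%) through the inverse logistic.
#' @return list of class \code{rating_effects}.
#' @export
rating_effects_config <- function(measure = c("intensity", "unpleasantness"),
                                  grand_mean = NULL,
                                  temp_effect = NULL,
                                  valence_effects = NULL,
                                  oxytocin_by_temp = NULL,
                                  threeway_neg_vs_pos_oxt_noxious = NULL,
                                  threeway_neg_vs_pos_placebo_noxious = NULL,
                                  baseline_mean = NULL,
                                  sd_subject_intercept = 10,
                                  sd_subject_slope = 10,
                                  sd_residual = 10,
                                  pain_midpoint = 46.33,
                                  pain_scale = 0.474) {
  measure <- match.arg(measure)
  def <- if (measure == "intensity") {
    list(grand_mean = 50, temp_effect = 47.8,
         valence_effects = c(negative = 1.51, neutral = 0, positive = -0.02,
                             scrambled = 1.5),
         oxytocin_by_temp = c(non_noxious = 3.54, noxious = -2.38),
         threeway_oxt = 1.53, threeway_placebo = 1.53,
         baseline_mean = 5)
  } else {
    list(grand_mean = 40, temp_effect = 50.1,
         valence_effects = c(negative = 2.31, neutral = 0, positive = -1.24,
                             scrambled = 1.0),
         oxytocin_by_temp = c(non_noxious = 0, noxious = 0),
         threeway_oxt = 7.08, threeway_placebo = 3.26,
         baseline_mean = 2)
  }
  out <- list(
    measure = measure,
    grand_mean = grand_mean %||% def$grand_mean,
    temp_effect = temp_effect %||% def$temp_effect,
    valence_effects = valence_effects %||% def$valence_effects,
    oxytocin_by_temp = oxytocin_by_temp %||% def$oxytocin_by_temp,
    threeway_neg_vs_pos_oxt_noxious =
      threeway_neg_vs_pos_oxt_noxious %||% def$threeway_oxt,
    threeway_neg_vs_pos_placebo_noxious =
      threeway_neg_vs_pos_placebo_noxious %||% def$threeway_placebo,
    baseline_mean = baseline_mean %||% def$baseline_mean,
    sd_subject_intercept = sd_subject_intercept,
    sd_subject_slope = sd_subject_slope,
    sd_residual = sd_residual,
    pain_midpoint = pain_midpoint,
    pain_scale = pain_scale)
  stopifnot(out$sd_subject_intercept >= 0, out$sd_subject_slope >= 0,
            out$sd_residual >= 0)
  class(out) <- "rating_effects"
  out
}

# Planted cell mean for one (medication, temperature, picture) cell.
rating_cell_mean <- function(cfg, medication, temperature, picture,
                             noxious_temp = 47.1, baseline_temp = 35.0) {
  v <- cfg$valence_effects[picture]
  if (temperature == baseline_temp) {
    return(unname(cfg$baseline_mean + v))
  }
  noxious <- temperature == noxious_temp
  mu <- cfg$grand_mean + ifelse(noxious, 0.5, -0.5) * cfg$temp_effect + v
  oxt_eff <- cfg$oxytocin_by_temp[[if (noxious) "noxious" else "non_noxious"]]
  mu <- mu + ifelse(medication == "oxytocin", 0.5, -0.5) * oxt_eff
  if (noxious && picture %in% c("negative", "positive")) {
    base_np <- cfg$valence_effects[["negative"]] - cfg$valence_effects[["positive"]]
    target <- if (medication == "oxytocin") {
      cfg$threeway_neg_vs_pos_oxt_noxious
    } else {
      cfg$threeway_neg_vs_pos_placebo_noxious
    }
    extra <- target - base_np
    mu <- mu + ifelse(picture == "negative", 0.5, -0.5) * extra
  }
  unname(mu)
}

#' Simulate trial-level rating tables
#'
#' Generates VAS intensity and unpleasantness ratings plus binary pain
#' judgments for every trial of a two-session medication crossover. Each
#' rating is the planted cell mean (see [rating_effects_config()]) plus a
#' by-subject random intercept, a by-subject random slope on the noxious-heat
#' indicator, and trial-level residual noise, truncated to [0, 100]. Binary
#' pain follows a logistic psychometric function of temperature.
#'
#' @param intensity,unpleasantness \code{rating_effects} configs for the two
#'   outcomes.
#' @param n_subjects number of subjects (>= 2).
#' @param seq_per_session optional \code{trial_sequence} supplying the trial
#'   order of every session; by default a balanced 36-trial design (12 cells x
#'   3 repetitions) is used.
#' @param reps repetitions per design cell when no sequence is given.
#' @param truncate truncate ratings to [0, 100] (default TRUE; switch off for
#'   exactness checks of the planted means).
#' @param noxious_temp,baseline_temp temperatures (degC) flagging the noxious
#'   and baseline levels.
#' @param seed integer seed.
#' @return data.frame of class \code{rating_table} with columns
#'   \code{subject}, \code{session}, \code{medication}, \code{temperature},
#'   \code{picture}, \code{rep}, \code{intensity}, \code{unpleasantness},
#'   \code{pain_binary}.
#' @examples
#' rt <- simulate_ratings(n_subjects = 4, seed = 9)
#' head(rt)
#' @export
simulate_ratings <- function(intensity = rating_effects_config("intensity"),
                             unpleasantness = rating_effects_config("unpleasantness"),
                             n_subjects = 30,
                             seq_per_session = NULL,
                             reps = 3L,
                             truncate = TRUE,
                             noxious_temp = 47.1,
                             baseline_temp = 35.0,
                             seed = 1L) {
  stopifnot(n_subjects >= 2)
  local_rng(seed)

  if (!is.null(seq_per_session)) {
    stopifnot(inherits(seq_per_session, "trial_sequence"))
    base <- seq_per_session$trials[, c("temperature", "picture")]
    base$rep <- stats::ave(seq_along(base$temperature),
                           base$temperature, base$picture, FUN = seq_along)
  } else {
    base <- expand.grid(temperature = c(baseline_temp, 44.7, noxious_temp),
                        picture = c("negative", "neutral", "positive",
                                    "scrambled"),
                        rep = seq_len(reps),
                        stringsAsFactors = FALSE)
  }

  rows <- vector("list", n_subjects * 2L)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    b0_i <- stats::rnorm(1, sd = intensity$sd_subject_intercept)
    bt_i <- stats::rnorm(1, sd = intensity$sd_subject_slope)
    b0_u <- stats::rnorm(1, sd = unpleasantness$sd_subject_intercept)
    bt_u <- stats::rnorm(1, sd = unpleasantness$sd_subject_slope)
    oxt_first <- s %% 2L == 0L
    for (ses in 1:2) {
      med <- if ((ses == 1L) == oxt_first) "oxytocin" else "placebo"
      tab <- base
      nox <- as.numeric(tab$temperature == noxious_temp)
      mu_i <- mapply(rating_cell_mean, medication = med,
                     temperature = tab$temperature, picture = tab$picture,
                     MoreArgs = list(cfg = intensity,
                                     noxious_temp = noxious_temp,
                                     baseline_temp = baseline_temp))
      mu_u <- mapply(rating_cell_mean, medication = med,
                     temperature = tab$temperature, picture = tab$picture,
                     MoreArgs = list(cfg = unpleasantness,
                                     noxious_temp = noxious_temp,
                                     baseline_temp = baseline_temp))
      n <- nrow(tab)
      val_i <- mu_i + b0_i + bt_i * nox +
        stats::rnorm(n, sd = intensity$sd_residual)
      val_u <- mu_u + b0_u + bt_u * nox +
        stats::rnorm(n, sd = unpleasantness$sd_residual)
      if (truncate) {
        val_i <- pmin(100, pmax(0, val_i))
        val_u <- pmin(100, pmax(0, val_u))
      }
      p_pain <- stats::plogis((tab$temperature - intensity$pain_midpoint) /
                                intensity$pain_scale)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = paste0("sub", s), session = ses, medication = med,
        temperature = tab$temperature, picture = tab$picture, rep = tab$rep,
        intensity = val_i, unpleasantness = val_u,
        pain_binary = stats::rbinom(n, 1, p_pain))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rating_table", "data.frame")
  out
}
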