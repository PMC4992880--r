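#' Factorial linear mixed model for ratings or heat estimates
#'
#' Fits the medication x temperature x valence factorial model on the
#' mean-centred, standardized outcome, with all factors and interactions as
#' fixed effects and a by-subject random-effects structure chosen from a
#' pre-declared ladder aiming at the maximal structure: full interaction
#' slopes (unstructured covariance), then main-effect slopes, then a random
#' intercept only. A rung is skipped when it has at least as many
#' random-effect columns as observations per subject (unidentifiable), and
#' abandoned on an optimizer error or convergence failure; boundary
#' (singular) fits are retained and flagged. Type III F-tests use
#' Kenward-Roger degrees of freedom when pbkrtest is available,
#' Satterthwaite otherwise; the method actually used is recorded.
#'
#' Rows outside the requested factor levels (the 35.0 degC baseline control
#' and scrambled pictures, by default) are dropped before fitting.
#'
#' @param table aggregated data.frame, one row per subject x condition.
#' @param outcome outcome column name (e.g. \code{"intensity"},
#'   \code{"unpleasantness"}, \code{"mhe"}).
#' @param temperature_levels numeric temperatures mapped to the two-level heat
#'   factor, in (non-noxious, noxious) order.
#' @param valence_col,valence_levels column and levels of the picture factor.
#' @param medication_levels levels of the medication factor (reference
#'   first).
#' @param random \code{"maximal"}, \code{"main_slopes"}, or
#'   \code{"intercept"}: the highest rung of the ladder to attempt.
#' @param ddf \code{"Kenward-Roger"} or \code{"Satterthwaite"}.
#' @return object of class \code{mixed_model_result}: \code{anova}
#'   (data.frame: term, df1, df2, F, p), \code{fit} (the lmerMod),
#'   \code{random_structure} (rung actually fitted), \code{singular},
#'   \code{ddf_method}, \code{outcome}, \code{center}, \code{scale},
#'   \code{data} (the analysis rows with the standardized outcome \code{.z}).
#' @export
fit_factorial_lmm <- function(table, outcome,
                              temperature_levels = c(44.7, 47.1),
                              valence_col = "picture",
                              valence_levels = c("negative", "neutral",
                                                 "positive"),
                              medication_levels = c("placebo", "oxytocin"),
                              random = c("maximal", "main_slopes",
                                         "intercept"),
                              ddf = c("Kenward-Roger", "Satterthwaite")) {
  random <- match.arg(random)
  ddf <- match.arg(ddf)
  stopifnot(outcome %in% names(table), valence_col %in% names(table),
            all(c("subject", "medication", "temperature") %in% names(table)))

  d <- table[table$temperature %in% temperature_levels &
               table[[valence_col]] %in% valence_levels &
               table$medication %in% medication_levels, , drop = FALSE]
  if (!nrow(d)) stop("fit_factorial_lmm: no rows left after level filtering")
  d$.temp <- factor(ifelse(d$temperature == temperature_levels[2],
                           "noxious", "non_noxious"),
                    levels = c("non_noxious", "noxious"))
  d$.med <- factor(d$medication, levels = medication_levels)
  d$.val <- factor(d[[valence_col]], levels = valence_levels)
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  z <- standardize_outcome(d[[outcome]])
  d$.z <- as.numeric(z)

  obs_per_subject <- min(table(d$subject))
  ladder <- c(maximal = ".med * .temp * .val",
              main_slopes = ".med + .temp + .val",
              intercept = "1")
  ladder <- ladder[match(random, names(ladder)):length(ladder)]
  re_cols <- vapply(ladder, function(tf) {
    ncol(stats::model.matrix(stats::as.formula(paste("~", tf)), d))
  }, 1L)

  fit <- NULL
  used <- NA_character_
  notes <- character(0)
  for (i in seq_along(ladder)) {
    rung <- names(ladder)[i]
    if (re_cols[i] >= obs_per_subject && rung != "intercept") {
      notes <- c(notes, paste0(rung, ": skipped (", re_cols[i],
                               " random-effect columns >= ", obs_per_subject,
                               " observations per subject)"))
      next
    }
    fml <- stats::as.formula(paste(
      ".z ~ .med * .temp * .val + (", ladder[i], "| subject)"))
    cand <- tryCatch(
      withCallingHandlers(
        lmerTest::lmer(fml, data = d, REML = TRUE,
                       contrasts = list(.med = "contr.sum",
                                        .temp = "contr.sum",
                                        .val = "contr.sum")),
        warning = function(w) {
          if (grepl("failed to converge", conditionMessage(w))) {
            stop("convergence failure: ", conditionMessage(w))
          }
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(cand, "error")) {
      notes <- c(notes, paste0(rung, ": ", conditionMessage(cand)))
      next
    }
    fit <- cand
    used <- rung
    break
  }
  if (is.null(fit)) {
    stop("fit_factorial_lmm: no rung of the random-effects ladder could be ",
         "fitted:\n", paste(notes, collapse = "\n"))
  }

  ddf_used <- ddf
  an <- tryCatch(stats::anova(fit, type = 3, ddf = ddf),
                 error = function(e) NULL)
  if (is.null(an)) {
    ddf_used <- "Satterthwaite"
    an <- stats::anova(fit, type = 3, ddf = ddf_used)
  }
  terms_pretty <- gsub("\\.med", "medication",
                       gsub("\\.temp", "temperature",
                            gsub("\\.val", "valence", rownames(an))))
  anova_df <- data.frame(term = terms_pretty,
                         df1 = an$NumDF, df2 = an$DenDF,
                         F = an$`F value`, p = an$`Pr(>F)`,
                         row.names = NULL)

  structure(list(anova = anova_df, fit = fit,
                 random_structure = used,
                 ladder_notes = notes,
                 singular = lme4::isSingular(fit),
                 ddf_method = ddf_used,
                 outcome = outcome,
                 center = attr(z, "center"), scale = attr(z, "scale"),
                 data = d),
            class = "mixed_model_result")
}

#' @exportS3Method base::print
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> outcome: ", x$outcome,
      " | random: ", x$random_structure,
      if (x$singular) " (singular)" else "",
      " | ddf: ", x$ddf_method, "\n", sep = "")
  df <- x$anova
  df$F <- round(df$F, 2)
  df$df2 <- round(df$df2, 1)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Estimated marginal means and pairwise contrasts for a model term
#'
#' Marginal means are averaged over the other factors with equal cell
#' weights; means and contrasts are reported both on the raw outcome scale
#' (VAS points or MHE units, back-converted through the stored
#' standardization) and as standardized effects (beta, in outcome SDs).
#'
#' @param result a \code{mixed_model_result}.
#' @param term character model term, e.g. \code{"temperature"},
#'   \code{"medication:temperature"}, or
#'   \code{"medication:temperature:valence"}.
#' @param confidence interval coverage.
#' @return list with \code{means} (term levels, raw-scale mean and CI, and
#'   standardized mean \code{beta}) and \code{contrasts} (pairwise
#'   differences with raw-scale estimate and CI, standardized \code{beta},
#'   and p value).
#' @export
marginal_means_contrasts <- function(result, term, confidence = 0.95) {
  stopifnot(inherits(result, "mixed_model_result"))
  internal <- gsub("medication", ".med",
                   gsub("temperature", ".temp",
                        gsub("valence", ".val", term)))
  vars <- strsplit(internal, ":", fixed = TRUE)[[1]]
  bad <- setdiff(vars, c(".med", ".temp", ".val"))
  if (length(bad)) {
    stop("marginal_means_contrasts: unknown term component(s): ",
         paste(gsub("^\\.", "", bad), collapse = ", "))
  }
  spec <- stats::as.formula(paste("~", paste(vars, collapse = " * ")))
  emm <- emmeans::emmeans(result$fit, spec, level = confidence,
                          lmer.df = if (result$ddf_method == "Kenward-Roger")
                            "kenward-roger" else "satterthwaite")
  ms <- as.data.frame(emm)
  sc <- result$scale
  ct <- result$center
  means <- data.frame(ms[vars],
                      mean = ms$emmean * sc + ct,
                      lower = ms$lower.CL * sc + ct,
                      upper = ms$upper.CL * sc + ct,
                      beta = ms$emmean)
  names(means)[seq_along(vars)] <- gsub("^\\.", "",
                                        c(".med" = "medication",
                                          ".temp" = "temperature",
                                          ".val" = "valence")[vars])
  pr <- as.data.frame(summary(graphics::pairs(emm, adjust = "none"),
                              infer = c(TRUE, TRUE), level = confidence))
  contrasts <- data.frame(contrast = pr$contrast,
                          estimate = pr$estimate * sc,
                          lower = pr$lower.CL * sc,
                          upper = pr$upper.CL * sc,
                          beta = pr$estimate,
                          se_beta = pr$SE,
                          df = pr$df,
                          p = pr$p.value)
  list(means = means, contrasts = contrasts)
}

#' Control analyses: scrambled factor, baseline temperature, pain proportions
#'
#' \describe{
#'   \item{scrambled_factor}{Refits the factorial mixed model with the
#'     three-level valence factor replaced by a two-level factor contrasting
#'     intact pictures (negative/neutral/positive) with scrambled pictures.}
#'   \item{baseline_only}{Restricts the table to the 35.0 degC control rows
#'     and fits a medication x picture mixed model (random intercept) to test
#'     sensitivity of the outcome to visual stimulation alone.}
#'   \item{pain_proportions}{Percentage of trials judged painful per
#'     temperature, from the binary pain column.}
#' }
#'
#' @param table aggregated (or, for \code{pain_proportions}, trial-level)
#'   data.frame.
#' @param mode one of \code{"scrambled_factor"}, \code{"baseline_only"},
#'   \code{"pain_proportions"}.
#' @param outcome outcome column for the model-based modes.
#' @param baseline_temp the control temperature in degC.
#' @param ... passed on to [fit_factorial_lmm()].
#' @return a \code{mixed_model_result} (model modes) or a data.frame with
#'   \code{temperature}, \code{n}, \code{n_painful}, \code{pct_painful}.
#' @export
control_analyses <- function(table,
                             mode = c("scrambled_factor", "baseline_only",
                                      "pain_proportions"),
                             outcome = "intensity",
                             baseline_temp = 35.0, ...) {
  mode <- match.arg(mode)
  if (mode == "pain_proportions") {
    if (!"pain_binary" %in% names(table)) {
      stop("control_analyses: pain_proportions needs a pain_binary column")
    }
    agg <- stats::aggregate(pain_binary ~ temperature, data = table,
                            FUN = function(v) c(n = length(v), k = sum(v)))
    out <- data.frame(temperature = agg$temperature,
                      n = agg$pain_binary[, "n"],
                      n_painful = agg$pain_binary[, "k"])
    out$pct_painful <- 100 * out$n_painful / out$n
    return(out)
  }
  if (mode == "scrambled_factor") {
    d <- table
    d$scrambled <- ifelse(d$picture == "scrambled", "scrambled", "pictures")
    return(fit_factorial_lmm(d, outcome,
                             valence_col = "scrambled",
                             valence_levels = c("pictures", "scrambled"),
                             ...))
  }
  # baseline_only
  d <- table[table$temperature == baseline_temp, , drop = FALSE]
  if (!nrow(d)) stop("control_analyses: no rows at the baseline temperature")
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  z <- standardize_outcome(d[[outcome]])
  d$.z <- as.numeric(z)
  d$.med <- factor(d$medication)
  d$.pic <- factor(d$picture)
  fit <- lmerTest::lmer(.z ~ .med * .pic + (1 | subject), data = d,
                        contrasts = list(.med = "contr.sum",
                                         .pic = "contr.sum"))
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  anova_df <- data.frame(
    term = gsub("\\.med", "medication", gsub("\\.pic", "picture",
                                             rownames(an))),
    df1 = an$NumDF, df2 = an$DenDF, F = an$`F value`, p = an$`Pr(>F)`,
    row.names = NULL)
  structure(list(anova = anova_df, fit = fit,
                 random_structure = "intercept", ladder_notes = character(0),
                 singular = lme4::isSingular(fit),
                 ddf_method = "Satterthwaite",
                 outcome = outcome,
                 center = attr(z, "center"), scale = attr(z, "scale"),
                 data = d),
            class = "mixed_model_result")
}
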