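#' Pipeline configuration
#'
#' Bundles every parameter and seed of a full simulated analysis run. A
#' single global seed deterministically derives one sub-seed per stage
#' (\code{seed * 97 + stage index}, kept inside the 32-bit integer range), so
#' each stage is independently reproducible.
#'
#' @param seed global integer seed.
#' @param n_voxels,grid_dim voxel count and NIfTI lattice (product must equal
#'   \code{n_voxels}).
#' @param active_fraction,effect_scale ground-truth pattern parameters
#'   (fraction of signal-carrying voxels; weight SD in signal units per
#'   degC).
#' @param n_train_subjects,train_temp_levels training-study size and
#'   temperature levels.
#' @param n_test_subjects test-study size.
#' @param noise_sd,subject_sd beta-level noise SDs.
#' @param alpha_grid,lambda_grid,variance_target decoder tuning grids and PCA
#'   retained-variance target.
#' @param n_rating_subjects rating-study size.
#' @param outlier_p two-tailed outlier probability (default 1/5000).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       n_voxels = 2000L,
                       grid_dim = c(10L, 10L, 20L),
                       active_fraction = 0.1,
                       effect_scale = 0.2,
                       n_train_subjects = 12L,
                       train_temp_levels = seq(42.3, 47.1, length.out = 8),
                       n_test_subjects = 30L,
                       noise_sd = 1,
                       subject_sd = 0.5,
                       alpha_grid = c(0.1, 0.5, 0.9, 1.0),
                       lambda_grid = 10^seq(-3, 1, length.out = 20),
                       variance_target = 0.999,
                       n_rating_subjects = 30L,
                       outlier_p = 1 / 5000) {
  stopifnot(prod(grid_dim) == n_voxels)
  cfg <- as.list(environment())
  cfg$stage_seeds <- stage_seeds(seed)
  class(cfg) <- "run_config"
  cfg
}

stage_seeds <- function(seed) {
  stages <- c("pattern", "train", "test", "ratings", "tune")
  s <- (as.numeric(seed) * 97 + seq_along(stages)) %% (.Machine$integer.max - 1)
  stats::setNames(as.integer(s) + 1L, stages)
}

#' Run the simulated analysis pipeline
#'
#' Executes the requested stages in dependency order on a shared
#' configuration: \code{simulate} (ground-truth pattern, training study, test
#' study, ratings), \code{train} (LOSO tuning + full refit of the weight
#' map), \code{apply} (multi-voxel heat estimates for the test study),
#' \code{evaluate} (recovery/validity metrics), \code{stats} (outlier rule,
#' aggregation, factorial mixed models for intensity, unpleasantness and MHE,
#' pain proportions). Later stages fail with an explicit message when an
#' earlier stage they depend on was not run. When \code{outdir} is given,
#' every stage writes its artifacts (TSV tables, NIfTI weight map, JSON
#' summary, and the configuration itself) into it.
#'
#' @param config a \code{run_config}.
#' @param stages character subset of
#'   \code{c("simulate", "train", "apply", "evaluate", "stats")}.
#' @param outdir optional output directory.
#' @param state optional result of a previous partial run, to supply upstream
#'   artifacts.
#' @return list of class \code{pipeline_result} with entries per stage and a
#'   \code{summary} list of headline numbers.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "train", "apply",
                                    "evaluate", "stats"),
                         outdir = NULL,
                         state = NULL) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "train", "apply", "evaluate", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  st <- if (is.null(state)) list(config = config) else state
  ss <- config$stage_seeds
  need <- function(what, stage, dep) {
    if (is.null(st[[what]])) {
      stop("run_pipeline: stage '", stage, "' needs artifact '", what,
           "' from stage '", dep, "', which has not been run")
    }
    st[[what]]
  }

  if ("simulate" %in% stages) {
    st$pattern <- make_ground_truth_pattern(
      config$n_voxels, config$active_fraction, config$effect_scale,
      seed = ss["pattern"])
    st$training_study <- simulate_training_study(
      config$n_train_subjects, config$train_temp_levels, st$pattern,
      noise_sd = config$noise_sd, subject_sd = config$subject_sd,
      seed = ss["train"])
    st$test_study <- simulate_test_study(
      config$n_test_subjects, pattern = st$pattern,
      noise_sd = config$noise_sd, subject_sd = config$subject_sd,
      seed = ss["test"])
    st$ratings <- simulate_ratings(n_subjects = config$n_rating_subjects,
                                   seed = ss["ratings"])
  }
  if ("train" %in% stages) {
    ts <- need("training_study", "train", "simulate")
    st$weight_map <- train_full(ts, config$alpha_grid, config$lambda_grid,
                                config$variance_target)
  }
  if ("apply" %in% stages) {
    wm <- need("weight_map", "apply", "train")
    te <- need("test_study", "apply", "simulate")
    st$mhe <- apply_weight_map(wm, te)
  }
  if ("evaluate" %in% stages) {
    wm <- need("weight_map", "evaluate", "train")
    mhe <- need("mhe", "evaluate", "apply")
    pat <- need("pattern", "evaluate", "simulate")
    st$evaluation <- recovery_report(wm, pat, mhe)
  }
  if ("stats" %in% stages) {
    rt <- need("ratings", "stats", "simulate")
    mhe <- need("mhe", "stats", "apply")
    st$stats <- list()
    keep <- rt
    for (m in c("intensity", "unpleasantness")) {
      rep <- flag_outliers(keep, m, p_two_tailed = config$outlier_p)
      if (length(rep$index)) keep[[m]][rep$index] <- NA
      st$stats[[paste0("outliers_", m)]] <- rep
    }
    agg <- aggregate_conditions(keep)
    st$stats$aggregated <- agg
    st$stats$intensity <- fit_factorial_lmm(agg, "intensity")
    st$stats$unpleasantness <- fit_factorial_lmm(agg, "unpleasantness")
    mhe_keep <- mhe
    rep <- flag_outliers(mhe_keep, "mhe", p_two_tailed = config$outlier_p)
    if (length(rep$index)) mhe_keep$mhe[rep$index] <- NA
    st$stats$outliers_mhe <- rep
    st$stats$mhe <- fit_factorial_lmm(mhe_keep, "mhe")
    st$stats$pain_proportions <- control_analyses(rt, "pain_proportions")
  }

  st$summary <- pipeline_summary(st)
  class(st) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_artifacts(st, outdir)
  st
}

pipeline_summary <- function(st) {
  s <- list()
  if (!is.null(st$weight_map)) {
    wm <- st$weight_map
    s$loso_cv_rmse <- wm$cv_error
    s$loso_r <- unname(stats::cor(wm$loso_predictions$predicted,
                                  wm$loso_predictions$temperature))
    s$alpha <- wm$alpha
    s$lambda <- wm$lambda
    s$n_nonzero_components <- wm$n_nonzero_components
  }
  if (!is.null(st$evaluation)) {
    ev <- st$evaluation
    s$weight_recovery_r <- ev$weight_correlation
    s$mhe_temperature_r <- ev$mhe_temperature$r
    s$median_split_accuracy <- ev$classification$accuracy
    s$median_split_precision <- ev$classification$precision
  }
  if (!is.null(st$stats)) {
    s$intensity_temperature_F <-
      st$stats$intensity$anova$F[st$stats$intensity$anova$term == "temperature"]
    s$unpleasantness_temperature_F <-
      st$stats$unpleasantness$anova$F[
        st$stats$unpleasantness$anova$term == "temperature"]
  }
  s
}

write_pipeline_artifacts <- function(st, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- st$config
  cfg_flat <- cfg[!vapply(cfg, is.list, TRUE)]
  jsonlite::write_json(cfg_flat, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(st$ratings)) {
    write_tsv(st$ratings, file.path(outdir, "ratings.tsv"))
  }
  if (!is.null(st$weight_map)) {
    write_weight_map(st$weight_map, file.path(outdir, "weight_map"),
                     grid_dim = cfg$grid_dim)
  }
  if (!is.null(st$mhe)) write_tsv(st$mhe, file.path(outdir, "mhe.tsv"))
  if (!is.null(st$stats)) {
    for (m in c("intensity", "unpleasantness", "mhe")) {
      write_tsv(st$stats[[m]]$anova,
                file.path(outdir, paste0("anova_", m, ".tsv")))
    }
    write_tsv(st$stats$pain_proportions,
              file.path(outdir, "pain_proportions.tsv"))
  }
  if (length(st$summary)) {
    jsonlite::write_json(st$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages run: ",
      paste(intersect(c("pattern", "weight_map", "mhe", "evaluation", "stats"),
                      names(x)[!vapply(x, is.null, TRUE)]), collapse = ", "),
      "\n", sep = "")
  if (length(x$summary)) utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}
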