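#' Beta-map container
#'
#' One subject's stack of per-condition GLM amplitudes: a condition x voxel
#' matrix plus the factor labels describing each row. The interchange object
#' between the first-level GLM and the multivoxel analysis.
#'
#' @param values condition x voxel numeric matrix.
#' @param condition_labels data.frame with one row per condition (columns such
#'   as \code{temperature}, \code{medication}, \code{picture}).
#' @param subject_id subject identifier.
#' @param mask logical vector over voxels (default all TRUE).
#' @return Object of class \code{beta_maps}.
#' @export
beta_maps <- function(values, condition_labels, subject_id,
                      mask = rep(TRUE, ncol(values))) {
  stopifnot(is.matrix(values), nrow(condition_labels) == nrow(values),
            length(mask) == ncol(values))
  if (any(!is.finite(values[, mask]))) {
    stop("beta_maps: non-finite values inside the mask")
  }
  structure(list(values = values, condition_labels = condition_labels,
                 subject_id = subject_id, mask = mask),
            class = "beta_maps")
}

#' @exportS3Method base::print
print.beta_maps <- function(x, ...) {
  cat("<beta_maps> subject ", x$subject_id, ": ", nrow(x$values),
      " conditions x ", ncol(x$values), " voxels\n", sep = "")
  invisible(x)
}

#' Simulate the pattern-training study
#'
#' Emulates the parallel training experiment: per subject, one beta map per
#' temperature level (eight levels by default, no pictures), whose expectation
#' is \code{temperature * pattern$weights} plus a subject-specific voxel
#' offset. By default beta maps are drawn directly at the beta level
#' (\code{method = "beta"}); \code{method = "bold"} instead synthesizes a full
#' BOLD run per subject and estimates the betas with [fit_glm()], as an
#' end-to-end integration path.
#'
#' @param n_subjects number of subjects (>= 3; LOSO-CV needs >= 3 folds).
#' @param temp_levels temperatures in degC; default 8 equally spaced levels
#'   spanning 42.3 to 47.1.
#' @param pattern a \code{ground_truth_pattern}.
#' @param noise_sd per-voxel beta-level noise SD (signal units).
#' @param subject_sd SD of the subject-specific per-voxel offset shared across
#'   temperature levels.
#' @param reps repetitions of each level when \code{method = "bold"}.
#' @param method \code{"beta"} (fast, default) or \code{"bold"} (simulate +
#'   GLM).
#' @param seed integer seed.
#' @return list of class \code{training_study}: \code{subjects} (list of
#'   \code{beta_maps}), \code{temp_levels}, \code{pattern}, \code{seed}.
#' @examples
#' pat <- make_ground_truth_pattern(200, seed = 3)
#' ts <- simulate_training_study(4, pattern = pat, seed = 3)
#' length(ts$subjects)
#' @export
simulate_training_study <- function(n_subjects,
                                    temp_levels = seq(42.3, 47.1, length.out = 8),
                                    pattern,
                                    noise_sd = 1,
                                    subject_sd = 0.5,
                                    reps = 1L,
                                    method = c("beta", "bold"),
                                    seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(pattern, "ground_truth_pattern"))
  if (n_subjects < 3L) {
    stop("simulate_training_study: need >= 3 subjects for LOSO-CV downstream")
  }
  if (n_subjects <= 5L) {
    warning("simulate_training_study: ", n_subjects,
            " subjects gives very few LOSO folds")
  }
  local_rng(seed)
  n_vox <- length(pattern$weights)
  n_lev <- length(temp_levels)

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    if (method == "beta") {
      offset <- stats::rnorm(n_vox, sd = subject_sd)
      E <- outer(temp_levels, pattern$weights) +
        matrix(offset, n_lev, n_vox, byrow = TRUE)
      vals <- E + matrix(stats::rnorm(n_lev * n_vox, sd = noise_sd),
                         n_lev, n_vox)
    } else {
      sseq <- generate_trial_sequence(
        temperatures = temp_levels, picture_conditions = "none",
        reps = reps, seed = sample.int(.Machine$integer.max, 1))
      run <- simulate_bold_run(
        sseq, pattern, noise_sd = noise_sd, ar1_rho = 0.3,
        seed = sample.int(.Machine$integer.max, 1))
      fit <- fit_glm(run, build_design_matrix(run))
      keep <- order(as.numeric(sub("\\|.*$", "", fit$condition_labels$condition)))
      vals <- fit$values[keep, , drop = FALSE]
      temp_levels_s <- as.numeric(sub("\\|.*$", "",
                                      fit$condition_labels$condition[keep]))
      stopifnot(isTRUE(all.equal(sort(temp_levels_s), sort(temp_levels))))
    }
    subjects[[s]] <- beta_maps(
      vals,
      condition_labels = data.frame(temperature = temp_levels),
      subject_id = paste0("train", s))
  }
  structure(list(subjects = subjects, temp_levels = temp_levels,
                 pattern = pattern, noise_sd = noise_sd, seed = seed),
            class = "training_study")
}

#' Simulate the factorial test study
#'
#' Per subject, one beta map for each of the 24 cells of the 2 (medication) x
#' 3 (temperature) x 4 (picture) design, with expectation \code{temperature *
#' pattern$weights} plus a subject voxel offset. An optional modulation adds
#' condition-specific signal along the pattern direction (or orthogonal to
#' it) for sensitivity analyses; without it, the expected multivoxel heat
#' estimate is identical across picture conditions at a fixed temperature.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param temperatures,pictures,medications factor levels of the design.
#' @param pattern a \code{ground_truth_pattern}.
#' @param noise_sd,subject_sd noise SDs as in [simulate_training_study()].
#' @param modulation optional list: \code{cells} a named numeric vector of
#'   signal amplitudes keyed \code{"medication|temperature|picture"}, and
#'   \code{mode} either \code{"aligned"} (along the unit-norm pattern) or
#'   \code{"orthogonal"}.
#' @param seed integer seed.
#' @return list of class \code{test_study}: \code{subjects} (list of
#'   \code{beta_maps} with 24 rows each), \code{design}, \code{pattern},
#'   \code{seed}.
#' @export
simulate_test_study <- function(n_subjects,
                                temperatures = c(35.0, 44.7, 47.1),
                                pictures = c("negative", "neutral",
                                             "positive", "scrambled"),
                                medications = c("placebo", "oxytocin"),
                                pattern,
                                noise_sd = 1,
                                subject_sd = 0.5,
                                modulation = NULL,
                                seed = 1L) {
  stopifnot(inherits(pattern, "ground_truth_pattern"), n_subjects >= 2)
  local_rng(seed)
  design <- expand.grid(medication = medications,
                        temperature = temperatures,
                        picture = pictures,
                        stringsAsFactors = FALSE)
  n_cond <- nrow(design)
  n_vox <- length(pattern$weights)

  mod_mat <- matrix(0, n_cond, n_vox)
  if (!is.null(modulation)) {
    mode <- match.arg(modulation$mode %||% "aligned",
                      c("aligned", "orthogonal"))
    w <- pattern$weights
    dir <- if (mode == "aligned") {
      w / sqrt(sum(w^2))
    } else {
      v <- stats::rnorm(n_vox)
      v <- v - w * sum(v * w) / sum(w^2)
      v / sqrt(sum(v^2))
    }
    keys <- paste(design$medication,
                  format(design$temperature, nsmall = 1, trim = TRUE),
                  design$picture, sep = "|")
    hit <- match(names(modulation$cells), keys)
    if (anyNA(hit)) {
      stop("simulate_test_study: unknown modulation cell(s): ",
           paste(names(modulation$cells)[is.na(hit)], collapse = ", "))
    }
    for (k in seq_along(hit)) {
      mod_mat[hit[k], ] <- mod_mat[hit[k], ] + modulation$cells[k] * dir
    }
  }

  E0 <- outer(design$temperature, pattern$weights) + mod_mat
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    offset <- stats::rnorm(n_vox, sd = subject_sd)
    vals <- E0 + matrix(offset, n_cond, n_vox, byrow = TRUE) +
      matrix(stats::rnorm(n_cond * n_vox, sd = noise_sd), n_cond, n_vox)
    subjects[[s]] <- beta_maps(vals, condition_labels = design,
                               subject_id = paste0("sub", s))
  }
  structure(list(subjects = subjects, design = design, pattern = pattern,
                 noise_sd = noise_sd, seed = seed),
            class = "test_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
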