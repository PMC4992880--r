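#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors (n >= 4, both with nonzero variance).
#' @param confidence interval coverage (default 0.95).
#' @return list with \code{r}, \code{ci} (length 2), \code{n}.
#' @examples
#' pearson_with_ci(1:10, (1:10) * 2 + rnorm(10, sd = .1))
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("pearson_with_ci: need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_with_ci: zero variance in x or y")
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - confidence) / 2) / sqrt(n - 3)
  list(r = r, ci = tanh(c(z - half, z + half)), n = n)
}

#' Median-split dichotomization
#'
#' Values strictly above the sample median are labeled positive; values at or
#' below the median are negative (ties at the median count as negative).
#'
#' @param values numeric vector (n >= 2, not all identical).
#' @return logical vector, TRUE = positive.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("median_split: need n >= 2")
  if (length(unique(values)) == 1L) {
    stop("median_split: all values identical; split is degenerate")
  }
  values > stats::median(values)
}

#' Binary classification report
#'
#' Confusion counts plus accuracy and precision, with the noxious class as the
#' positive class by convention.
#'
#' @param predicted,truth logical (or coercible) vectors, TRUE = positive.
#' @param positive_class label stored in the report.
#' @return list of class \code{classification_report}: \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{n}, \code{accuracy}, \code{precision}
#'   (NA with a flag when no positives are predicted),
#'   \code{positive_class}.
#' @export
classification_report <- function(predicted, truth,
                                  positive_class = "noxious") {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  stopifnot(length(predicted) == length(truth))
  if (!length(predicted)) stop("classification_report: empty input")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  n <- length(predicted)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 accuracy = (tp + tn) / n,
                 precision = precision,
                 precision_undefined = tp + fp == 0,
                 positive_class = positive_class),
            class = "classification_report")
}

#' @exportS3Method base::print
print.classification_report <- function(x, ...) {
  cat("<classification_report> n = ", x$n,
      ", accuracy = ", sprintf("%.1f%%", 100 * x$accuracy),
      ", precision = ",
      if (is.na(x$precision)) "undefined" else sprintf("%.1f%%", 100 * x$precision),
      " (positive: ", x$positive_class, ")\n", sep = "")
  invisible(x)
}

#' Parameter-recovery summary for a trained weight map
#'
#' Collects the validity metrics for a simulated run: the correlation between
#' recovered and planted voxel weights, the pooled correlation between
#' multi-voxel heat estimates and temperature, and the median-split
#' classification of noxious (47.1 degC) versus non-noxious (44.7 degC)
#' conditions.
#'
#' @param map a \code{heat_weight_map}.
#' @param truth the \code{ground_truth_pattern} that generated the data.
#' @param mhe an \code{mhe_table} with a \code{temperature} column.
#' @param noxious_temp,nonnoxious_temp temperatures (degC) defining the
#'   classification contrast.
#' @return list of class \code{recovery_report}: \code{weight_correlation},
#'   \code{mhe_temperature} (a [pearson_with_ci()] result), and
#'   \code{classification} (a \code{classification_report}).
#' @export
recovery_report <- function(map, truth, mhe,
                            noxious_temp = 47.1, nonnoxious_temp = 44.7) {
  stopifnot(inherits(map, "heat_weight_map"),
            inherits(truth, "ground_truth_pattern"))
  if (length(map$w_vox) != length(truth$weights)) {
    stop("recovery_report: weight map and ground-truth grids differ")
  }
  wcor <- stats::cor(map$w_vox, truth$weights)
  rtemp <- pearson_with_ci(mhe$mhe, mhe$temperature)
  sel <- mhe$temperature %in% c(noxious_temp, nonnoxious_temp)
  sub <- mhe[sel, , drop = FALSE]
  cls <- classification_report(median_split(sub$mhe),
                               sub$temperature == noxious_temp,
                               positive_class = paste0(noxious_temp, " degC"))
  structure(list(weight_correlation = wcor,
                 mhe_temperature = rtemp,
                 classification = cls),
            class = "recovery_report")
}

#' @exportS3Method base::print
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n",
      "  weight recovery r = ", sprintf("%.3f", x$weight_correlation), "\n",
      "  MHE ~ temperature r = ", sprintf("%.3f", x$mhe_temperature$r),
      " [", sprintf("%.3f", x$mhe_temperature$ci[1]), ", ",
      sprintf("%.3f", x$mhe_temperature$ci[2]), "]\n",
      "  median-split accuracy = ",
      sprintf("%.1f%%", 100 * x$classification$accuracy), "\n", sep = "")
  invisible(x)
}
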