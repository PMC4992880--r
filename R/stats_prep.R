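#' Flag extreme ratings within subject and temperature
#'
#' Values whose two-tailed normal probability within their
#' (subject, temperature) group falls below \code{p_two_tailed} are flagged as
#' outliers: the threshold is \code{z* = qnorm(1 - p/2)} (about 3.719 for the
#' default 1:5000 rule) and a row is flagged when |z| computed from its
#' group's own mean and SD exceeds z*. Groups with fewer than 3 rows or zero
#' SD are skipped with a warning.
#'
#' @param table data.frame of trial- or condition-level rows.
#' @param measure column name to screen.
#' @param grouping columns defining the screening groups (default subject and
#'   temperature).
#' @param p_two_tailed two-tailed tail probability (default 1/5000).
#' @param leave_one_out if TRUE, each row's z uses the group mean/SD computed
#'   without that row; the default includes the candidate value.
#' @return list of class \code{outlier_report}: \code{flagged} (data.frame of
#'   flagged rows with their z), \code{index} (row indices into \code{table}),
#'   \code{threshold}, \code{flagged_fraction}, \code{skipped_groups}.
#' @export
flag_outliers <- function(table, measure,
                          grouping = c("subject", "temperature"),
                          p_two_tailed = 1 / 5000,
                          leave_one_out = FALSE) {
  if (!measure %in% names(table)) {
    stop("flag_outliers: unknown measure '", measure, "'")
  }
  stopifnot(all(grouping %in% names(table)), p_two_tailed > 0,
            p_two_tailed < 1)
  zstar <- stats::qnorm(1 - p_two_tailed / 2)
  key <- interaction(table[grouping], drop = TRUE)
  x <- table[[measure]]
  z <- rep(NA_real_, length(x))
  skipped <- character(0)
  for (g in levels(key)) {
    idx <- which(key == g)
    xi <- x[idx]
    if (length(idx) < 3 || stats::sd(xi, na.rm = TRUE) == 0 ||
        is.na(stats::sd(xi, na.rm = TRUE))) {
      skipped <- c(skipped, g)
      next
    }
    if (leave_one_out) {
      z[idx] <- vapply(seq_along(idx), function(i) {
        rest <- xi[-i]
        (xi[i] - mean(rest)) / stats::sd(rest)
      }, numeric(1))
    } else {
      z[idx] <- (xi - mean(xi)) / stats::sd(xi)
    }
  }
  if (length(skipped)) {
    warning("flag_outliers: skipped ", length(skipped),
            " group(s) with < 3 rows or zero SD")
  }
  hit <- which(!is.na(z) & abs(z) > zstar)
  flagged <- cbind(table[hit, c(grouping, measure), drop = FALSE],
                   z = z[hit])
  structure(list(flagged = flagged, index = hit, threshold = zstar,
                 measure = measure,
                 flagged_fraction = length(hit) / nrow(table),
                 skipped_groups = skipped),
            class = "outlier_report")
}

#' Aggregate surviving repetitions to one row per design cell
#'
#' Arithmetic mean of the given measures over repetitions within each
#' subject x medication x temperature x picture cell; cells whose repetitions
#' were all excluded come out as missing (NA).
#'
#' @param table trial-level data.frame (outlier rows already removed).
#' @param measures columns to average.
#' @param by grouping columns defining a cell.
#' @return data.frame with one row per observed cell.
#' @export
aggregate_conditions <- function(table,
                                 measures = c("intensity", "unpleasantness"),
                                 by = c("subject", "medication",
                                        "temperature", "picture")) {
  stopifnot(all(by %in% names(table)))
  measures <- intersect(measures, names(table))
  agg <- stats::aggregate(table[measures], by = table[by],
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg[do.call(order, agg[by]), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Mean-center and standardize an outcome
#'
#' @param values numeric vector with nonzero SD.
#' @return numeric vector with mean 0 and sample SD 1; attributes
#'   \code{center} and \code{scale} store the transform for back-conversion of
#'   effect sizes (a 1-SD standardized effect equals \code{scale} raw units).
#' @export
standardize_outcome <- function(values) {
  mu <- mean(values, na.rm = TRUE)
  sd <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(sd) || sd == 0) {
    stop("standardize_outcome: outcome has zero SD")
  }
  structure((values - mu) / sd, center = mu, scale = sd)
}
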