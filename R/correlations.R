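# Per-dataset correlations between log-transformed diversity and stability
# metrics, with the sign convention that positive reported r always means
# "diversity stabilizes populations".

# y metrics that measure instability (CVs): reported r = -Pearson.
.cv_metrics <- c("upcv", "wpcv", "upcv_detrended", "wpcv_detrended",
                 "upcv_d", "upcv_s", "upcv_r")
.popsize_metrics <- c("popsize_d", "popsize_s", "popsize_r")
.diversity_metrics <- c("average_richness", "cumulative_richness", "turnover")

#' Fisher's Z transform of a correlation coefficient
#'
#' @param r Correlation with `|r| < 1`.
#' @param n Number of plots the correlation is based on (>= 4).
#' @return List with `z = atanh(r)` and `var = 1/(n - 3)`.
#' @export
#' @examples
#' fisher_transform(0.5, 28) # z = atanh(0.5), var = 1/25
fisher_transform <- function(r, n) {
  if (abs(r) >= 1)
    stop("|r| = 1 gives infinite Fisher z; clamp or exclude", call. = FALSE)
  if (n < 4) stop("Fisher variance 1/(n-3) needs n >= 4", call. = FALSE)
  list(z = atanh(r), var = 1 / (n - 3))
}

#' Sign-adjusted correlation between two metrics for one dataset
#'
#' Computes the Pearson correlation between the natural-log-transformed
#' metrics across the dataset's plots. Plots where either metric is missing
#' or non-positive are dropped pairwise. For instability (CV) y-metrics the
#' reported r is the negated raw correlation, so positive values always mean
#' a stabilizing diversity effect; for population-size y-metrics the raw sign
#' is kept. Datasets with fewer than `min_plots` usable plots, or with no
#' variation in either metric, are excluded (return `NULL`). A correlation of
#' exactly +/-1 is clamped to +/-0.999999 before the Fisher transform, with a
#' warning.
#'
#' @param pm Plot-metrics data frame for one dataset (see [plot_metrics()]).
#' @param x_metric Diversity metric column: `"average_richness"`,
#'   `"cumulative_richness"` or `"turnover"`.
#' @param y_metric Stability-side metric column (a CV or a group population
#'   size).
#' @param min_plots Minimum usable plots (default 5).
#' @return One-row data frame (`dataset_id`, `x_metric`, `y_metric`,
#'   `r_raw`, `r`, `n_plots`, `fisher_z`, `z_var`, `p_value`, `significant`),
#'   or `NULL` with attribute-free silent exclusion.
#' @export
dataset_correlation <- function(pm, x_metric, y_metric, min_plots = 5) {
  stopifnot(x_metric %in% names(pm), y_metric %in% names(pm))
  x <- pm[[x_metric]]
  y <- pm[[y_metric]]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n <- sum(ok)
  if (n < min_plots) return(NULL)
  lx <- log(x[ok])
  ly <- log(y[ok])
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NULL)
  r_raw <- stats::cor(lx, ly)
  r <- if (y_metric %in% .cv_metrics) -r_raw else r_raw
  r_f <- r
  if (abs(r_f) > 0.999999) {
    warning("|r| = 1 clamped to 0.999999 for the Fisher transform")
    r_f <- sign(r_f) * 0.999999
  }
  fz <- fisher_transform(r_f, max(n, 4))
  tstat <- abs(r_raw) * sqrt((n - 2) / max(1 - r_raw^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  data.frame(
    dataset_id = pm$dataset_id[1],
    x_metric = x_metric, y_metric = y_metric,
    r_raw = r_raw, r = r, n_plots = n,
    fisher_z = fz$z, z_var = fz$var,
    p_value = p, significant = p < 0.05
  )
}

#' Per-dataset correlations for all requested metric pairs
#'
#' @param pm Plot-metrics data frame (all datasets).
#' @param x_metrics Diversity metrics to use (default all three).
#' @param y_metrics Stability-side metrics to use (default the overall and
#'   group CVs plus group population sizes).
#' @param min_plots Minimum usable plots per dataset (default 5).
#' @return Data frame of [dataset_correlation()] rows, with an
#'   `"exclusions"` attribute (data frame `dataset_id`, `x_metric`,
#'   `y_metric`, `reason`) recording dropped dataset-pair combinations.
#' @export
correlate_datasets <- function(pm,
                               x_metrics = .diversity_metrics,
                               y_metrics = c(.cv_metrics[1:2],
                                             .cv_metrics[5:7],
                                             .popsize_metrics),
                               min_plots = 5) {
  res <- list()
  excl <- list()
  for (did in unique(pm$dataset_id)) {
    sub <- pm[pm$dataset_id == did, , drop = FALSE]
    for (xm in x_metrics) {
      for (ym in y_metrics) {
        row <- dataset_correlation(sub, xm, ym, min_plots)
        if (is.null(row)) {
          usable <- sum(is.finite(sub[[xm]]) & is.finite(sub[[ym]]) &
                          sub[[xm]] > 0 & sub[[ym]] > 0)
          reason <- if (usable < min_plots) {
            sprintf("fewer than %d usable plots", min_plots)
          } else "no variation across plots"
          excl[[length(excl) + 1L]] <- data.frame(
            dataset_id = did, x_metric = xm, y_metric = ym, reason = reason)
        } else {
          res[[length(res) + 1L]] <- row
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(dataset_id = character(), x_metric = character(),
               y_metric = character(), r_raw = numeric(), r = numeric(),
               n_plots = integer(), fisher_z = numeric(), z_var = numeric(),
               p_value = numeric(), significant = logical())
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dataset_id = character(), x_metric = character(),
               y_metric = character(), reason = character())
  out
}
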