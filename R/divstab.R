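# The main fitting function: records in, cross-dataset synthesis out.

#' Fit the diversity-population stability analysis to an abundance table
#'
#' Runs the full analysis on a long-format community abundance table:
#' per-plot stability and diversity metrics ([plot_metrics()]), per-dataset
#' sign-adjusted correlations of every diversity metric (average richness,
#' cumulative richness, temporal turnover) against the stability-side
#' metrics ([correlate_datasets()]), and two cross-dataset syntheses — a
#' REML linear mixed-effects model with a diversity-by-stability metric
#' interaction on the core 2 x 2 combinations
#' ([fit_metric_interaction_model()]) and a REML random-effects
#' meta-regression per combination ([meta_by_combination()]). Group-level
#' analyses (dominant / subordinate / rare stability and population size)
#' and the subgroup-vs-overall comparison are included. If a covariate table
#' is supplied, climate variables are reduced to two principal components and
#' a driver regression is fitted for each core metric combination.
#'
#' @param records Long-format abundance table (`dataset_id`, `plot_id`,
#'   `year`, `species_id`, `abundance`).
#' @param covariates Optional per-dataset covariate table with columns
#'   `dataset_id`, `abundance_metric`, `plot_size_m2`, `duration_years`,
#'   `management_coverage` and `climate_*` columns.
#' @param occurrence_threshold Occurrence filter for stability metrics
#'   (default 0.30; 0.10 and 0.20 are the usual robustness alternatives).
#' @param detrend Use detrended CVs (three-term local variance) for the core
#'   synthesis? Default `FALSE`.
#' @param min_plots Minimum usable plots per dataset (default 5).
#' @param rare_cutoff Rare-species relative-abundance cutoff (default 0.05).
#' @param richness_filtered Compute richness on occurrence-filtered species
#'   only? Default `FALSE`.
#' @return Object of class `"divstab"`: a list with `plot_metrics`,
#'   `correlations` (with an `exclusions` attribute), `synthesis` (the mixed
#'   model on the core combinations), `meta` (pooled estimates per
#'   combination), `subgroup` (overall-vs-group R-squared fits), `drivers`
#'   and `climate_pca` (when covariates are given), and `settings`.
#' @export
#' @examples
#' sim <- simulate_collection(sim_config(n_datasets = 6,
#'   plots_per_dataset = 10, years_per_plot = 10, pool_size = 15, seed = 1))
#' fit <- divstab(sim$records)
#' summary(fit)
divstab <- function(records, covariates = NULL,
                    occurrence_threshold = 0.3, detrend = FALSE,
                    min_plots = 5, rare_cutoff = 0.05,
                    richness_filtered = FALSE) {
  if (occurrence_threshold < 0 || occurrence_threshold > 1)
    stop("occurrence_threshold must lie in [0, 1]", call. = FALSE)
  if (min_plots < 2) stop("min_plots must be >= 2", call. = FALSE)
  pm <- plot_metrics(records, threshold = occurrence_threshold,
                     rare_cutoff = rare_cutoff,
                     richness_filtered = richness_filtered)
  core_y <- if (detrend) c("upcv_detrended", "wpcv_detrended") else
    c("upcv", "wpcv")
  y_all <- unique(c(core_y, "upcv", "wpcv", "upcv_d", "upcv_s", "upcv_r",
                    "popsize_d", "popsize_s", "popsize_r"))
  corr <- correlate_datasets(pm, y_metrics = y_all, min_plots = min_plots)
  core <- corr[corr$x_metric %in% c("average_richness",
                                    "cumulative_richness") &
                 corr$y_metric %in% core_y, , drop = FALSE]
  synthesis <- if (nrow(core) && length(unique(core$dataset_id)) >= 2 &&
                     length(unique(core$x_metric)) == 2 &&
                     length(unique(core$y_metric)) == 2 &&
                     all(table(core$x_metric, core$y_metric) > 0)) {
    fit_metric_interaction_model(core)
  } else NULL
  meta <- if (nrow(corr)) meta_by_combination(corr) else NULL
  subgroup <- synth_subgroups(corr, core_y)
  drv <- NULL
  pca <- NULL
  if (!is.null(covariates)) {
    clim_cols <- grep("^climate_", names(covariates), value = TRUE)
    cov <- covariates
    if (length(clim_cols) >= 2 && nrow(cov) >= 3) {
      pca <- climate_pca(cov[, clim_cols, drop = FALSE])
      cov$climate_pc1 <- pca$scores[, 1]
      cov$climate_pc2 <- pca$scores[, 2]
    }
    agg <- stats::aggregate(average_richness ~ dataset_id, data = pm, mean)
    names(agg)[2] <- "mean_average_richness"
    cov <- merge(cov, agg, by = "dataset_id")
    cov$log_plot_size <- log(cov$plot_size_m2)
    cov$log_duration <- log(cov$duration_years)
    drv <- list()
    for (xm in c("average_richness", "cumulative_richness")) {
      for (ym in core_y) {
        sub <- corr[corr$x_metric == xm & corr$y_metric == ym, ]
        dd <- merge(sub, cov, by = "dataset_id")
        if (nrow(dd) >= 10) {
          drv[[paste(xm, ym, sep = ".")]] <-
            tryCatch(drivers_regression(dd), error = function(e) e$message)
        }
      }
    }
  }
  structure(list(
    plot_metrics = pm,
    correlations = corr,
    synthesis = synthesis,
    meta = meta,
    subgroup = subgroup,
    drivers = drv,
    climate_pca = pca,
    settings = list(occurrence_threshold = occurrence_threshold,
                    detrend = detrend, min_plots = min_plots,
                    rare_cutoff = rare_cutoff,
                    richness_filtered = richness_filtered,
                    core_y = core_y)
  ), class = "divstab")
}

# Subgroup-vs-overall comparisons: unweighted stability against rare-species
# stability, weighted against dominant-species stability, pairing r values
# by (dataset, diversity metric).
synth_subgroups <- function(corr, core_y) {
  pair_r <- function(y1, y2) {
    a <- corr[corr$y_metric == y1 & corr$x_metric != "turnover", ]
    b <- corr[corr$y_metric == y2 & corr$x_metric != "turnover", ]
    m <- merge(a[, c("dataset_id", "x_metric", "r")],
               b[, c("dataset_id", "x_metric", "r")],
               by = c("dataset_id", "x_metric"))
    if (nrow(m) < 3) return(NULL)
    tryCatch(subgroup_vs_overall(m$r.x, m$r.y), error = function(e) NULL)
  }
  list(unweighted_vs_rare = pair_r(core_y[1], "upcv_r"),
       weighted_vs_dominant = pair_r(core_y[2], "upcv_d"))
}

#' @export
print.divstab <- function(x, ...) {
  cat("Diversity-population stability analysis\n")
  cat(sprintf("  plots: %d in %d datasets; occurrence threshold %.2f%s\n",
              nrow(x$plot_metrics),
              length(unique(x$plot_metrics$dataset_id)),
              x$settings$occurrence_threshold,
              if (x$settings$detrend) " (detrended CVs)" else ""))
  cat(sprintf("  per-dataset correlations: %d rows (%d excluded)\n",
              nrow(x$correlations),
              nrow(attr(x$correlations, "exclusions"))))
  if (!is.null(x$synthesis))
    cat(sprintf("  metric interaction: F(%g, %.1f) = %.2f, p = %.3g\n",
                x$synthesis$interaction$df1, x$synthesis$interaction$df2,
                x$synthesis$interaction$F, x$synthesis$interaction$p))
  invisible(x)
}

#' @export
summary.divstab <- function(object, ...) {
  out <- list(settings = object$settings,
              interaction = object$synthesis$interaction,
              emm = object$synthesis$emm,
              meta = object$meta,
              subgroup = object$subgroup)
  class(out) <- "summary.divstab"
  out
}

#' @export
print.summary.divstab <- function(x, ...) {
  cat("Cross-dataset synthesis of diversity-stability correlations\n\n")
  if (!is.null(x$interaction))
    cat(sprintf("Diversity x stability metric interaction: F(%g, %.1f) = %.2f, p = %.3g\n\n",
                x$interaction$df1, x$interaction$df2, x$interaction$F,
                x$interaction$p))
  if (!is.null(x$emm)) {
    cat("Mixed-model estimated marginal mean r per combination:\n")
    print(x$emm, digits = 3)
    cat("\n")
  }
  if (!is.null(x$meta)) {
    cat("Random-effects meta-analysis (pooled r, tau^2) per combination:\n")
    print(x$meta[, c("x_metric", "y_metric", "k", "pooled_r",
                     "ci_lo", "ci_hi", "tau2", "p")], digits = 3)
  }
  sg <- x$subgroup
  if (!is.null(sg$unweighted_vs_rare))
    cat(sprintf("\nR^2 unweighted-stability r ~ rare-group r: %.2f\n",
                sg$unweighted_vs_rare$r_squared))
  if (!is.null(sg$weighted_vs_dominant))
    cat(sprintf("R^2 weighted-stability r ~ dominant r:     %.2f\n",
                sg$weighted_vs_dominant$r_squared))
  invisible(x)
}

#' Pooled correlation coefficients of a fitted analysis
#'
#' @param object A `"divstab"` fit.
#' @param which `"meta"` (default) for meta-analytic pooled r per
#'   combination, `"emm"` for mixed-model estimated marginal means of the
#'   core combinations.
#' @param ... Unused.
#' @return Named numeric vector (`x_metric:y_metric` names).
#' @export
coef.divstab <- function(object, which = c("meta", "emm"), ...) {
  which <- match.arg(which)
  if (which == "meta") {
    stats::setNames(object$meta$pooled_r,
                    paste(object$meta$x_metric, object$meta$y_metric,
                          sep = ":"))
  } else {
    stats::setNames(object$synthesis$emm$emmean,
                    paste(object$synthesis$emm$x_metric,
                          object$synthesis$emm$y_metric, sep = ":"))
  }
}

#' Histograms of per-dataset correlation coefficients
#'
#' One panel per core metric combination, marking the meta-analytic pooled
#' mean.
#'
#' @param x A `"divstab"` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.divstab <- function(x, ...) {
  corr <- x$correlations
  core <- expand.grid(xm = c("average_richness", "cumulative_richness"),
                      ym = x$settings$core_y, stringsAsFactors = FALSE)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(core))) {
    sub <- corr[corr$x_metric == core$xm[i] & corr$y_metric == core$ym[i], ]
    graphics::hist(sub$r, breaks = 20, xlim = c(-1, 1),
                   main = paste(core$xm[i], "vs", core$ym[i]),
                   xlab = "r (sign-adjusted)", col = "grey80", ...)
    mrow <- x$meta[x$meta$x_metric == core$xm[i] &
                     x$meta$y_metric == core$ym[i], ]
    if (nrow(mrow)) graphics::abline(v = mrow$pooled_r, col = "red", lwd = 2)
  }
  invisible(x)
}
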