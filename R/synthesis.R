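# Cross-dataset synthesis: mixed-effects model with metric interaction,
# random-effects meta-regression on Fisher-Z effect sizes, driver regressions
# with VIF screening, climate PCA, and subgroup-vs-overall comparison.

#' Mixed-effects synthesis of per-dataset correlations
#'
#' Fits, by REML, `r ~ x_metric * y_metric + (1 | dataset_id)` to the
#' per-dataset correlation coefficients, treating the dataset as a random
#' intercept. The diversity-by-stability interaction is tested with an
#' F-statistic whose denominator degrees of freedom use the Satterthwaite
#' approximation (typically fractional). Estimated marginal means per metric
#' combination, with Satterthwaite-t 95% confidence intervals, summarize the
#' pooled correlation for each combination.
#'
#' @param corr Correlation table ([correlate_datasets()] rows) restricted to
#'   the metric combinations of interest; every combination must occur.
#' @param response Response column, default `"r"` (the sign-adjusted
#'   correlation; the meta-analytic route works on Fisher z instead).
#' @return Object of class `"divstab_synthesis"`: list with `model` (the
#'   `lmerModLmerTest` fit), `anova` (Satterthwaite F table), `interaction`
#'   (list `F`, `df1`, `df2`, `p`), and `emm` (data frame `x_metric`,
#'   `y_metric`, `emmean`, `se`, `df`, `lower`, `upper`, `p`).
#' @export
fit_metric_interaction_model <- function(corr, response = "r") {
  stopifnot(all(c("dataset_id", "x_metric", "y_metric", response) %in%
                  names(corr)))
  if (length(unique(corr$x_metric)) < 2 || length(unique(corr$y_metric)) < 2)
    stop("singular design: need >= 2 diversity and >= 2 stability metrics",
         call. = FALSE)
  tab <- table(corr$x_metric, corr$y_metric)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop("singular design: no observations for combination(s) ",
         paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(
    y = corr[[response]],
    x_metric = factor(corr$x_metric),
    y_metric = factor(corr$y_metric),
    dataset_id = factor(corr$dataset_id)
  )
  fit <- lmerTest::lmer(y ~ x_metric * y_metric + (1 | dataset_id),
                        data = dat, REML = TRUE)
  av <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  ia <- av["x_metric:y_metric", ]
  emm <- emmeans::emmeans(fit, ~ x_metric * y_metric,
                          lmer.df = "satterthwaite")
  es <- as.data.frame(summary(emm, infer = c(TRUE, TRUE)))
  out <- list(
    model = fit,
    anova = av,
    interaction = list(F = ia[["F value"]], df1 = ia[["NumDF"]],
                       df2 = ia[["DenDF"]], p = ia[["Pr(>F)"]]),
    emm = data.frame(
      x_metric = as.character(es$x_metric),
      y_metric = as.character(es$y_metric),
      emmean = es$emmean, se = es$SE, df = es$df,
      lower = es$lower.CL, upper = es$upper.CL,
      p = es$p.value
    )
  )
  class(out) <- "divstab_synthesis"
  out
}

#' @export
print.divstab_synthesis <- function(x, ...) {
  cat("Mixed-effects synthesis of per-dataset correlations\n")
  cat(sprintf("Interaction: F(%g, %.1f) = %.3f, p = %.4g\n",
              x$interaction$df1, x$interaction$df2,
              x$interaction$F, x$interaction$p))
  cat("Estimated marginal means:\n")
  print(x$emm, digits = 3)
  invisible(x)
}

#' Random-effects meta-analysis of Fisher-Z effect sizes
#'
#' Pools one metric combination's per-dataset effect sizes with a REML
#' random-effects model: between-dataset variance tau^2 is estimated by
#' restricted maximum likelihood and studies are weighted by
#' `1/(z_var + tau^2)`. The pooled mean and its 95% CI are back-transformed
#' to the correlation scale with `tanh`.
#'
#' @param z Fisher-Z effect sizes, one per dataset (>= 2).
#' @param v Sampling variances (`1/(n_plots - 3)`), all > 0.
#' @return List with `k`, `pooled_z`, `se`, `ci_z` (length 2), `tau2`, `p`,
#'   `pooled_r`, `ci_r`.
#' @export
random_effects_meta <- function(z, v) {
  if (length(z) < 2) stop("need >= 2 datasets to pool", call. = FALSE)
  if (length(v) != length(z)) stop("z and v lengths differ", call. = FALSE)
  if (any(v <= 0)) stop("all sampling variances must be > 0", call. = FALSE)
  fit <- metafor::rma(yi = z, vi = v, method = "REML")
  list(
    k = fit$k,
    pooled_z = as.numeric(fit$beta),
    se = fit$se,
    ci_z = c(fit$ci.lb, fit$ci.ub),
    tau2 = fit$tau2,
    p = fit$pval,
    pooled_r = tanh(as.numeric(fit$beta)),
    ci_r = tanh(c(fit$ci.lb, fit$ci.ub))
  )
}

#' Meta-analytic pooling for every metric combination in a correlation table
#'
#' @param corr [correlate_datasets()] output.
#' @return Data frame with one row per (x_metric, y_metric): `k`, `pooled_z`,
#'   `tau2`, `pooled_r`, `ci_lo`, `ci_hi`, `p`.
#' @export
meta_by_combination <- function(corr) {
  combos <- unique(corr[, c("x_metric", "y_metric")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- corr[corr$x_metric == combos$x_metric[i] &
                  corr$y_metric == combos$y_metric[i], ]
    if (nrow(sub) < 2) return(NULL)
    m <- random_effects_meta(sub$fisher_z, sub$z_var)
    data.frame(x_metric = combos$x_metric[i], y_metric = combos$y_metric[i],
               k = m$k, pooled_z = m$pooled_z, tau2 = m$tau2,
               pooled_r = m$pooled_r, ci_lo = m$ci_r[1], ci_hi = m$ci_r[2],
               p = m$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Driver regression for one metric combination
#'
#' Ordinary least squares of the per-dataset correlation coefficient on
#' dataset-level covariates: abundance-metric type (reference level
#' `"cover"`), log plot size, log study duration, management coverage, mean
#' average richness, and the first two climate principal components (those
#' present in `data` are used). Variance inflation factors are reported for
#' every predictor; a rank-deficient design is an error naming the aliased
#' columns.
#'
#' @param data Data frame with the response and predictor columns.
#' @param response Response column name (default `"r"`).
#' @param predictors Predictor column names; default: the intersection of
#'   `abundance_metric`, `log_plot_size`, `log_duration`,
#'   `management_coverage`, `mean_average_richness`, `climate_pc1`,
#'   `climate_pc2` with `names(data)`.
#' @return List with `model` (lm), `coefficients` (estimate, 95% CI, p per
#'   term) and `vif` (named vector; generalized VIF for factors).
#' @export
drivers_regression <- function(data, response = "r", predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- intersect(
      c("abundance_metric", "log_plot_size", "log_duration",
        "management_coverage", "mean_average_richness",
        "climate_pc1", "climate_pc2"),
      names(data))
  }
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  if (nrow(data) < 10)
    stop("driver regression needs >= 10 datasets", call. = FALSE)
  if ("abundance_metric" %in% predictors)
    data$abundance_metric <- stats::relevel(factor(data$abundance_metric),
                                            ref = "cover")
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  al <- stats::alias(fit)
  if (!is.null(al$Complete))
    stop("rank-deficient design; aliased: ",
         paste(rownames(al$Complete), collapse = ", "), call. = FALSE)
  vifs <- if (length(predictors) > 1) {
    v <- car::vif(fit)
    if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  } else stats::setNames(1, predictors)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(
    model = fit,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], lower = ci[, 1], upper = ci[, 2],
                              p = cf[, 4], row.names = NULL),
    vif = vifs
  )
}

#' Principal component analysis of dataset-level climate variables
#'
#' Standardizes each climate variable to zero mean and unit variance and
#' eigendecomposes the correlation matrix. A constant variable cannot be
#' standardized and is reported by name as an error.
#'
#' @param x Data frame or matrix, datasets in rows, >= 2 climate variables in
#'   columns, no missing values.
#' @return List with `scores` (datasets x components), `variance_fraction`
#'   (per component), and `loadings`.
#' @export
climate_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs >= 3 datasets", call. = FALSE)
  if (ncol(x) < 2) stop("PCA needs >= 2 variables", call. = FALSE)
  if (anyNA(x)) stop("climate table contains missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant climate variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  list(scores = pc$x,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation)
}

#' Relate overall-metric correlations to a group-level metric's correlations
#'
#' Regresses, across datasets, the r values obtained with an overall
#' stability metric on those obtained with a group-level metric (e.g.
#' unweighted stability vs rare-species stability) and reports the fit's
#' R-squared and p-value.
#'
#' @param overall,group Paired numeric vectors of r values (>= 3 pairs).
#' @return List with `r_squared`, `p`, `slope`, `n`.
#' @export
subgroup_vs_overall <- function(overall, group) {
  ok <- is.finite(overall) & is.finite(group)
  overall <- overall[ok]
  group <- group[ok]
  if (length(overall) < 3) stop("need >= 3 paired r values", call. = FALSE)
  if (stats::sd(overall) == 0 || stats::sd(group) == 0)
    stop("zero variance in r values: fit undefined", call. = FALSE)
  fit <- stats::lm(overall ~ group)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       slope = unname(stats::coef(fit)[2]),
       n = length(overall))
}
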