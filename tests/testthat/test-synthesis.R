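# Synthetic correlation tables with known structure for the synthesis stage.
make_corr <- function(n_datasets, effects, res_sd = 0.1, dataset_sd = 0) {
  combos <- expand.grid(x_metric = c("average_richness",
                                     "cumulative_richness"),
                        y_metric = c("upcv", "wpcv"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n_datasets), function(d) {
    u <- rnorm(1, 0, dataset_sd)
    data.frame(dataset_id = sprintf("D%03d", d),
               x_metric = combos$x_metric, y_metric = combos$y_metric,
               r = effects + u + rnorm(4, 0, res_sd))
  })
  do.call(rbind, rows)
}

test_that("with no dataset variance and balanced data the mixed model collapses to cell means", {
  set.seed(21)
  corr <- make_corr(40, effects = c(0.2, -0.1, 0.05, -0.3), res_sd = 0.05)
  fit <- suppressMessages(fit_metric_interaction_model(corr))
  cellmeans <- aggregate(r ~ x_metric + y_metric, data = corr, mean)
  m <- merge(fit$emm, cellmeans, by = c("x_metric", "y_metric"))
  expect_equal(m$emmean, m$r, tolerance = 1e-6)
  # Satterthwaite denominator df cannot exceed N - p
  expect_lte(fit$interaction$df2, nrow(corr) - 4)
  expect_gte(fit$interaction$F, 0)
})

test_that("a planted metric interaction is detected and estimated", {
  set.seed(22)
  base <- c(0.1, 0.1, 0.1, 0.1)
  delta <- 0.3 # added only to the (cumulative, wpcv) cell
  eff <- base + c(0, 0, 0, delta)
  corr <- make_corr(100, effects = eff, res_sd = 0.1, dataset_sd = 0.05)
  fit <- fit_metric_interaction_model(corr)
  emm <- fit$emm
  cell <- function(x, y) emm$emmean[emm$x_metric == x & emm$y_metric == y]
  est <- cell("cumulative_richness", "wpcv") - cell("average_richness", "wpcv") -
    (cell("cumulative_richness", "upcv") - cell("average_richness", "upcv"))
  expect_lt(abs(est - delta), 0.05)
  expect_lt(fit$interaction$p, 0.001)
})

test_that("a combination absent everywhere is a model-degeneracy error", {
  set.seed(23)
  corr <- make_corr(10, effects = rep(0, 4))
  corr <- corr[!(corr$x_metric == "cumulative_richness" &
                   corr$y_metric == "wpcv"), ]
  expect_error(fit_metric_interaction_model(corr), "singular design")
})

test_that("meta-analysis pools as closed forms dictate in degenerate cases", {
  # identical effect sizes: pooled = common value, tau2 = 0
  m <- random_effects_meta(rep(0.3, 6), rep(0.05, 6))
  expect_equal(m$pooled_z, 0.3)
  expect_equal(m$tau2, 0)
  # equal variances: pooled = arithmetic mean
  m2 <- random_effects_meta(c(0.1, 0.3), c(0.04, 0.04))
  expect_equal(m2$pooled_z, 0.2, tolerance = 1e-8)
  expect_equal(m2$pooled_r, tanh(0.2), tolerance = 1e-8)
  expect_error(random_effects_meta(c(0.1, 0.2), c(0.1, 0)), "> 0")
  expect_error(random_effects_meta(0.1, 0.1), ">= 2")
})

test_that("meta-analysis recovers planted heterogeneity and mean", {
  set.seed(24)
  k <- 200
  v <- runif(k, 0.02, 0.08)
  # plant the heterogeneity exactly: standardize both layers so the
  # between-dataset variance is 0.04 by construction, not just in expectation
  u <- rnorm(k); u <- (u - mean(u)) / sd(u) * sqrt(0.04)
  e <- rnorm(k); e <- (e - mean(e)) / sd(e)
  z <- 0.2 + u + e * sqrt(v)
  m <- random_effects_meta(z, v)
  expect_lt(abs(m$tau2 - 0.04), 0.015)
  expect_lt(abs(m$pooled_z - 0.2), 0.03)
  # pooled estimate lies within the span of its inputs
  expect_gte(m$pooled_z, min(z))
  expect_lte(m$pooled_z, max(z))
})

test_that("driver regression reports unit VIFs under orthogonality and flags rank deficiency", {
  # orthogonal centered predictors via QR of a random matrix
  set.seed(25)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 3), 60, 3))))[, 2:4]
  d <- data.frame(r = rnorm(60), p1 = q[, 1], p2 = q[, 2], p3 = q[, 3])
  out <- drivers_regression(d, predictors = c("p1", "p2", "p3"))
  expect_equal(unname(out$vif), rep(1, 3), tolerance = 1e-8)
  # duplicated predictor column
  d$p4 <- d$p1
  expect_error(drivers_regression(d, predictors = c("p1", "p2", "p3", "p4")),
               "rank-deficient")
})

test_that("driver regression recovers a planted coefficient", {
  set.seed(26)
  n <- 200
  d <- data.frame(
    r = NA, abundance_metric = sample(c("cover", "biomass", "frequency"),
                                      n, replace = TRUE),
    log_plot_size = rnorm(n), log_duration = rnorm(n),
    management_coverage = runif(n, 0, 100),
    mean_average_richness = rnorm(n, 20, 5),
    climate_pc1 = rnorm(n), climate_pc2 = rnorm(n))
  d$r <- 0.05 * d$mean_average_richness + rnorm(n, 0, 0.05)
  out <- drivers_regression(d)
  est <- out$coefficients$estimate[
    out$coefficients$term == "mean_average_richness"]
  expect_lt(abs(est - 0.05), 0.02)
  expect_true(all(out$vif < 2))
  # cover is the reference level: no "cover" dummy appears
  expect_false(any(grepl("abundance_metriccover", out$coefficients$term)))
})

test_that("climate PCA standardizes, names constant variables, and sums variance to one", {
  set.seed(27)
  x <- data.frame(a = rnorm(200), b = rnorm(200))
  x$c <- x$a * 3 + 5 # perfectly correlated with a
  p2 <- climate_pca(x[, c("a", "c")])
  expect_equal(p2$variance_fraction[1], 1)
  p <- climate_pca(x[, c("a", "b")])
  expect_equal(unname(p$variance_fraction),
               c(0.5, 0.5), tolerance = 0.05)
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)
  x$flat <- 1
  expect_error(climate_pca(x), "flat")
  expect_error(climate_pca(x[1:2, 1:2]), ">= 3")
})

test_that("subgroup-overall comparison reports R-squared as constructed", {
  expect_equal(suppressWarnings(subgroup_vs_overall(1:10, 1:10))$r_squared, 1)
  set.seed(28)
  a <- rnorm(1e4)
  expect_lt(subgroup_vs_overall(a, rnorm(1e4))$r_squared, 0.01)
  # construction with population R^2 = 0.64
  x <- rnorm(500)
  y <- 0.8 * x + rnorm(500, 0, sqrt(0.36))
  fit <- subgroup_vs_overall(y, x)
  expect_lt(abs(fit$r_squared - 0.64), 0.08)
  expect_error(subgroup_vs_overall(rep(1, 5), 1:5), "zero variance")
})
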