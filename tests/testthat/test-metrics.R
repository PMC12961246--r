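test_that("species temporal statistics follow the n-1 convention", {
  s <- species_temporal_stats(c(2, 2, 2))
  expect_equal(c(s$mu, s$sigma, s$cv), c(2, 0, 0))
  s <- species_temporal_stats(c(1, 2, 3))
  expect_equal(c(s$mu, s$sigma, s$cv), c(2, 1, 0.5))
  s <- species_temporal_stats(c(0, 5, 5, 0, 5))
  expect_equal(s$occurrence_fraction, 0.6)
  expect_equal(s$mu, 3)
  expect_error(species_temporal_stats(c(0, 0, 0)), "all-zero")
  expect_error(species_temporal_stats(5), ">= 2")
})

test_that("three-term local variance removes affine trends and is unbiased for iid noise", {
  expect_equal(ttlv(c(1, 2, 3, 4)), 0)
  expect_equal(ttlv(5 - 0.3 * (1:17)), 0)
  expect_equal(ttlv(c(0, 1, 0)), 2 / 3)
  expect_error(ttlv(c(1, 2)), ">= 3")
  set.seed(31)
  x <- rnorm(1e4, mean = 10, sd = 1)
  expect_equal(ttlv(x), 1, tolerance = 0.05)
  # invariance under adding any affine function of time
  tt <- seq_along(x)
  expect_equal(ttlv(x + 2.5 - 0.01 * tt), ttlv(x), tolerance = 1e-8)
})

test_that("occurrence filter retains species at or above the year fraction", {
  m <- cbind(a = c(rep(1, 3), rep(0, 7)),   # 3 of 10 years
             b = c(rep(1, 2), rep(0, 8)),   # 2 of 10 years
             c = rep(0, 10),                # never present
             d = rep(1, 10))
  expect_identical(occurrence_filter(m, 0.3), c("a", "d"))
  expect_identical(occurrence_filter(m, 0), c("a", "b", "d"))
  expect_error(occurrence_filter(m, 1.2), "threshold")
})

test_that("raising the occurrence threshold never grows the retained set", {
  set.seed(12)
  for (i in 1:50) {
    m <- random_small_plot()
    r10 <- occurrence_filter(m, 0.10)
    r20 <- occurrence_filter(m, 0.20)
    r30 <- occurrence_filter(m, 0.30)
    expect_true(all(r30 %in% r20))
    expect_true(all(r20 %in% r10))
  }
})

test_that("dominance classification applies the 5% rule with one dominant", {
  p <- c(A = 0.60, B = 0.30, C = 0.06, D = 0.04)
  expect_identical(classify_groups(p),
                   c(A = "dominant", B = "subordinate", C = "subordinate",
                     D = "rare"))
  expect_identical(unname(classify_groups(c(only = 1))), "dominant")
  # ties break to the lexicographically smallest id, independent of order
  g1 <- classify_groups(c(B = 0.5, A = 0.5))
  g2 <- classify_groups(c(A = 0.5, B = 0.5))
  expect_identical(g1[["A"]], "dominant")
  expect_identical(g2[["A"]], "dominant")
  expect_identical(g1[["B"]], "subordinate")
  # a dominant with p < cutoff stays dominant
  g <- classify_groups(c(a = 0.04, b = 0.03, rep(0.93 / 31, 31) |>
                           setNames(sprintf("z%02d", 1:31))))
  expect_identical(unname(g[["a"]]), "dominant")
})

test_that("richness and turnover count presences as specified", {
  m <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  colnames(m) <- c("A", "B", "C")
  r <- richness_and_turnover(m)
  expect_equal(r$average_richness, 2)
  expect_equal(r$cumulative_richness, 3)
  expect_equal(r$turnover, 1.5)
  full <- matrix(1, 4, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(richness_and_turnover(full)$turnover, 1)
  expect_error(richness_and_turnover(matrix(0, 3, 2,
                                            dimnames = list(NULL, c("a", "b")))),
               "ever present")
})

test_that("plot metrics reproduce the hand-computed UPCV/WPCV example", {
  # two species with cv (0.5, 0.3) and mu (3, 1): p = (0.75, 0.25)
  a <- c(1.5, 3, 4.5)            # mu 3, sd 1.5, cv 0.5
  b <- c(0.7, 1, 1.3)            # mu 1, sd 0.3, cv 0.3
  m <- cbind(a = a, b = b)
  pm <- compute_plot_metrics(m, threshold = 0.3)
  expect_equal(pm$upcv, 0.4)
  expect_equal(pm$wpcv, 0.5 * 0.75 + 0.3 * 0.25)
  expect_equal(pm$n_retained, 2L)
  # equal means: UPCV = WPCV
  m2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  pm2 <- compute_plot_metrics(m2)
  expect_equal(pm2$upcv, pm2$wpcv)
  # single retained species: everything collapses to its cv
  m3 <- cbind(a = c(1, 2, 3))
  pm3 <- compute_plot_metrics(m3)
  expect_equal(pm3$upcv, 0.5)
  expect_equal(pm3$wpcv, 0.5)
  expect_equal(pm3$upcv_d, 0.5)
  expect_true(is.na(pm3$upcv_s) && is.na(pm3$upcv_r))
})

test_that("richness is reported even when no species survives the filter", {
  m <- cbind(a = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  pm <- compute_plot_metrics(m, threshold = 0.3)
  expect_true(is.na(pm$upcv))
  expect_equal(pm$cumulative_richness, 1)
  expect_equal(pm$n_retained, 0L)
})

test_that("UPCV and WPCV are convex combinations of retained species CVs", {
  set.seed(77)
  for (i in 1:200) {
    m <- random_small_plot()
    o <- oracle_plot_cvs(m)
    if (is.null(o)) next
    pm <- compute_plot_metrics(m)
    expect_gte(pm$upcv, min(o$cv) - 1e-12)
    expect_lte(pm$upcv, max(o$cv) + 1e-12)
    expect_gte(pm$wpcv, min(o$cv) - 1e-12)
    expect_lte(pm$wpcv, max(o$cv) + 1e-12)
    expect_gte(pm$cumulative_richness, pm$average_richness)
    expect_gte(pm$turnover, 1)
  }
})

test_that("turnover equals 1 exactly when no recorded species is ever absent", {
  set.seed(88)
  for (i in 1:100) {
    m <- random_small_plot()
    pm <- compute_plot_metrics(m)
    present <- m[, colSums(m > 0) > 0, drop = FALSE]
    no_absence <- all(present > 0)
    expect_identical(isTRUE(all.equal(pm$turnover, 1)), no_absence)
  }
})

test_that("UPCV, WPCV and TTLV match the brute-force oracle on random plots", {
  set.seed(123)
  n_checked <- 0
  for (i in 1:300) {
    m <- random_small_plot()
    pm <- compute_plot_metrics(m)
    u <- oracle_upcv(m)
    if (is.na(u)) {
      expect_true(is.na(pm$upcv))
      next
    }
    expect_equal(pm$upcv, u, tolerance = 1e-10)
    expect_equal(pm$wpcv, oracle_wpcv(m), tolerance = 1e-10)
    expect_equal(ttlv(m[, 1]), oracle_ttlv(m[, 1]), tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("with Taylor exponent below 2 the dominant is more stable than rare species", {
  sim <- default_collection()
  pm <- default_fit()$plot_metrics
  ok <- is.finite(pm$upcv_d) & is.finite(pm$upcv_r)
  expect_lt(mean(pm$upcv_d[ok]), mean(pm$upcv_r[ok]))
})

test_that("plot_metrics handles long tables with omitted zero records", {
  rec <- data.frame(
    dataset_id = "D1", plot_id = "P1",
    year = c(1, 1, 2, 3, 2, 3),
    species_id = c("a", "b", "a", "a", "b", "b"),
    abundance = c(1, 4, 2, 3, 5, 6))
  pm <- plot_metrics(rec)
  expect_equal(pm$upcv, mean(c(sd(1:3) / 2, sd(4:6) / 5)))
  # omitting a zero record is the same as an explicit zero
  rec0 <- rbind(rec, data.frame(dataset_id = "D1", plot_id = "P1", year = 1,
                                species_id = "c", abundance = 3))
  recNA <- rbind(rec0, data.frame(dataset_id = "D1", plot_id = "P1",
                                  year = c(2, 3), species_id = "c",
                                  abundance = c(0, 0)))
  expect_equal(plot_metrics(rec0), plot_metrics(recNA))
})
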