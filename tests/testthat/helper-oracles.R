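# Brute-force oracles, written independently of the package internals:
# explicit loops, no shared helpers, so a formula mistake in R/ cannot be
# mirrored here.

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Unweighted mean population CV over retained columns of a years x species
# matrix, occurrence filter applied by explicit counting.
oracle_plot_cvs <- function(mat, threshold = 0.3) {
  keep <- character(0)
  for (sp in colnames(mat)) {
    n_occ <- 0
    for (t in seq_len(nrow(mat))) if (mat[t, sp] > 0) n_occ <- n_occ + 1
    if (n_occ > 0 && n_occ / nrow(mat) >= threshold) keep <- c(keep, sp)
  }
  if (!length(keep)) return(NULL)
  mus <- cvs <- numeric(length(keep))
  for (i in seq_along(keep)) {
    x <- mat[, keep[i]]
    mus[i] <- oracle_mean(x)
    cvs[i] <- oracle_sd(x) / mus[i]
  }
  list(species = keep, mu = mus, cv = cvs)
}

oracle_upcv <- function(mat, threshold = 0.3) {
  o <- oracle_plot_cvs(mat, threshold)
  if (is.null(o)) return(NA_real_)
  oracle_mean(o$cv)
}

oracle_wpcv <- function(mat, threshold = 0.3) {
  o <- oracle_plot_cvs(mat, threshold)
  if (is.null(o)) return(NA_real_)
  total <- sum(o$mu)
  s <- 0
  for (i in seq_along(o$cv)) s <- s + o$cv[i] * (o$mu[i] / total)
  s
}

# Three-term local variance by direct triplet summation.
oracle_ttlv <- function(x) {
  n <- length(x)
  acc <- 0
  for (t in 2:(n - 1)) acc <- acc + (x[t - 1] - 2 * x[t] + x[t + 1])^2
  acc / (6 * (n - 2))
}

# A random small plot matrix (<= 6 species, <= 8 years) guaranteed to have
# at least one species with at least one positive abundance.
random_small_plot <- function() {
  ny <- sample(3:8, 1)
  ns <- sample(1:6, 1)
  m <- matrix(stats::rpois(ny * ns, lambda = 2) *
                stats::rbinom(ny * ns, 1, 0.7), ny, ns,
              dimnames = list(NULL, sprintf("sp%02d", seq_len(ns))))
  m[1, 1] <- m[1, 1] + 1
  m
}

# Shared synthetic collection for the heavier cross-stage tests, built once
# per test run at the generator's default study conditions.
.fixture_env <- new.env(parent = emptyenv())

default_collection <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_collection(sim_config(seed = 20260923L))
  }
  .fixture_env$sim
}

default_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- default_collection()
    .fixture_env$fit <- divstab(sim$records, sim$covariates)
  }
  .fixture_env$fit
}
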