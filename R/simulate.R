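# Synthetic multi-dataset community generator.
#
# The generative model per species is a latent Gaussian AR(1) scaled to a
# target mean mu and SD sqrt(a * mu^b) (Taylor's power law), plus an optional
# linear trend, truncated at a detection limit so that low-abundance species
# show absences. Truncation couples occupancy to mean abundance, which is what
# drives temporal turnover downstream.

#' Configuration for the synthetic community generator
#'
#' Bundles and validates every parameter of [simulate_collection()]. Defaults
#' describe a moderately sized multi-site collection of permanent vegetation
#' plots: 50 datasets of 30 plots sampled for 15 years, each dataset drawing
#' from a pool of 40 species whose mean abundances follow a lognormal
#' dominance hierarchy, with variance-mean scaling below the Poisson-squared
#' regime (`taylor_b < 2`) so that abundant species are intrinsically the more
#' stable ones.
#'
#' @param n_datasets Number of datasets (sites) in the collection.
#' @param plots_per_dataset Plots per dataset; a single count, or a length-2
#'   range from which each dataset's plot count is drawn uniformly.
#' @param years_per_plot Sampling years per plot; at least 3 (the detrended
#'   CV needs three consecutive points).
#' @param pool_size Species pool size per dataset. `0` yields an empty
#'   collection.
#' @param logmean_mu,logmean_sd Meanlog and sdlog of the lognormal
#'   distribution from which species mean abundances are drawn (abundance
#'   units; e.g. percent cover).
#' @param taylor_a,taylor_b Taylor power-law parameters: the temporal variance
#'   of a species with mean \eqn{\mu} is \eqn{a \mu^b}. `taylor_a > 0`,
#'   `taylor_b` in \[0, 4\].
#' @param ar_phi Lag-1 autocorrelation of the latent fluctuations, in \[0, 1).
#' @param detection_limit Abundances strictly below this value are recorded
#'   as 0 (non-detection). Non-negative.
#' @param trend_sd SD of per-species linear trend slopes (abundance units per
#'   year). Non-negative.
#' @param plot_scale_sd sdlog of the lognormal plot-level productivity factor
#'   multiplying all species means within a plot; creates between-plot
#'   variation in richness and stability within a dataset.
#' @param species_plot_sd sdlog of the lognormal species-by-plot deviation of
#'   mean abundance (microhabitat response); creates compositional
#'   differences between plots so that cumulative richness varies within a
#'   dataset.
#' @param seed Integer seed; the whole collection is a deterministic function
#'   of the configuration including the seed.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_collection()], [simulate_plot_series()]
#' @export
#' @examples
#' cfg <- sim_config(n_datasets = 2, plots_per_dataset = 5, years_per_plot = 8)
#' sim <- simulate_collection(cfg)
#' head(sim$records)
sim_config <- function(n_datasets = 50, plots_per_dataset = 30,
                       years_per_plot = 15, pool_size = 40,
                       logmean_mu = 1, logmean_sd = 1.2,
                       taylor_a = 0.5, taylor_b = 1.7,
                       ar_phi = 0.3, detection_limit = 0.2,
                       trend_sd = 0.02, plot_scale_sd = 0.4,
                       species_plot_sd = 0.5, seed = 42L) {
  stopifnot(length(plots_per_dataset) %in% c(1L, 2L))
  if (n_datasets < 1 || any(plots_per_dataset < 1))
    stop("n_datasets and plots_per_dataset must be >= 1", call. = FALSE)
  if (years_per_plot < 3)
    stop("years_per_plot must be >= 3 (detrended CV needs >= 3 points)",
         call. = FALSE)
  if (pool_size < 0) stop("pool_size must be >= 0", call. = FALSE)
  if (taylor_a <= 0) stop("taylor_a must be > 0", call. = FALSE)
  if (taylor_b < 0 || taylor_b > 4)
    stop("taylor_b must lie in [0, 4]", call. = FALSE)
  if (ar_phi < 0 || ar_phi >= 1)
    stop("ar_phi must lie in [0, 1)", call. = FALSE)
  if (detection_limit < 0) stop("detection_limit must be >= 0", call. = FALSE)
  if (trend_sd < 0) stop("trend_sd must be >= 0", call. = FALSE)
  if (plot_scale_sd < 0) stop("plot_scale_sd must be >= 0", call. = FALSE)
  if (species_plot_sd < 0) stop("species_plot_sd must be >= 0", call. = FALSE)
  structure(list(
    n_datasets = as.integer(n_datasets),
    plots_per_dataset = as.integer(plots_per_dataset),
    years_per_plot = as.integer(years_per_plot),
    pool_size = as.integer(pool_size),
    logmean_mu = logmean_mu, logmean_sd = logmean_sd,
    taylor_a = taylor_a, taylor_b = taylor_b,
    ar_phi = ar_phi, detection_limit = detection_limit,
    trend_sd = trend_sd, plot_scale_sd = plot_scale_sd,
    species_plot_sd = species_plot_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic child seed for hierarchical streams (collection -> dataset ->
# plot). LCG-style mix kept in [0, 2^31 - 2] so set.seed() accepts it.
child_seed <- function(parent, i) {
  as.integer((as.double(parent) * 48271 + as.double(i) * 16807 + 1) %%
               2147483646)
}

#' Simulate one plot's multi-species abundance time series
#'
#' Draws, for each species mean \eqn{\mu_i}, a latent standard-normal AR(1)
#' series with lag-1 correlation `ar_phi`, scales it to mean \eqn{\mu_i} and
#' SD \eqn{\sqrt{a \mu_i^b}}, adds a linear trend with slope drawn from
#' `Normal(0, trend_sd)` (centred on the mid-year so the temporal mean is
#' unchanged), and finally records values below `detection_limit` as 0.
#' Randomness is taken from the current RNG state; call `set.seed()` first
#' for reproducibility.
#'
#' @param species_means Positive numeric vector of species mean abundances.
#' @param config A [sim_config()] object (only the noise parameters are used).
#' @param n_years Number of years to simulate (default
#'   `config$years_per_plot`); at least 3.
#'
#' @return A numeric matrix with `n_years` rows and one column per species
#'   (named after `names(species_means)` if present), all entries >= 0.
#' @export
simulate_plot_series <- function(species_means, config,
                                 n_years = config$years_per_plot) {
  if (any(species_means <= 0) || anyNA(species_means))
    stop("all species means must be positive", call. = FALSE)
  if (n_years < 3) stop("n_years must be >= 3", call. = FALSE)
  s <- length(species_means)
  phi <- config$ar_phi
  eps <- matrix(stats::rnorm(n_years * s), n_years, s)
  z <- eps
  if (phi > 0 && n_years > 1) {
    w <- sqrt(1 - phi^2)
    for (t in 2:n_years) z[t, ] <- phi * z[t - 1, ] + w * eps[t, ]
  }
  sds <- sqrt(config$taylor_a * species_means^config$taylor_b)
  slopes <- stats::rnorm(s, 0, config$trend_sd)
  tt <- seq_len(n_years) - (n_years + 1) / 2
  x <- rep(species_means, each = n_years) + z * rep(sds, each = n_years) +
    outer(tt, slopes)
  x[x < config$detection_limit | x < 0] <- 0
  colnames(x) <- names(species_means)
  x
}

#' Simulate a multi-dataset collection of community time series
#'
#' Generates a long-format abundance table emulating a collection of
#' repeatedly sampled permanent vegetation plots, together with a per-dataset
#' covariate table (abundance-metric type, plot size, duration, management
#' coverage, and four correlated synthetic climate variables driven by two
#' latent factors, so a downstream principal-component step has structure to
#' find).
#'
#' Random streams are hierarchical: the collection seed spawns one stream per
#' dataset, which spawns one stream per plot, so enlarging the collection
#' does not perturb already-generated datasets or plots. Identical
#' configurations (including the seed) yield identical tables.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list with elements `records` (data frame: `dataset_id`,
#'   `plot_id`, `year`, `species_id`, `abundance`; absences stored as explicit
#'   zeros) and `covariates` (one row per dataset).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pool_size == 0L) {
    return(list(
      records = data.frame(dataset_id = character(), plot_id = character(),
                           year = integer(), species_id = character(),
                           abundance = numeric()),
      covariates = data.frame(dataset_id = character(),
                              abundance_metric = character(),
                              plot_size_m2 = numeric(),
                              duration_years = integer(),
                              management_coverage = numeric())
    ))
  }
  nd <- config$n_datasets
  ny <- config$years_per_plot
  sp_ids <- sprintf("sp%03d", seq_len(config$pool_size))
  # loadings of the 4 climate variables on 2 latent climate factors
  clim_load <- rbind(c(0.9, 0.1), c(0.8, -0.3), c(-0.2, 0.9), c(0.3, 0.8))
  rec_list <- vector("list", nd)
  cov_list <- vector("list", nd)
  for (d in seq_len(nd)) {
    ds_seed <- child_seed(config$seed, d)
    set.seed(ds_seed)
    did <- sprintf("D%03d", d)
    mu <- stats::rlnorm(config$pool_size, config$logmean_mu, config$logmean_sd)
    names(mu) <- sp_ids
    np <- if (length(config$plots_per_dataset) == 2L) {
      sample(config$plots_per_dataset[1]:config$plots_per_dataset[2], 1L)
    } else config$plots_per_dataset
    fac <- stats::rnorm(2)
    clim <- drop(clim_load %*% fac) + 0.4 * stats::rnorm(4)
    cov_list[[d]] <- data.frame(
      dataset_id = did,
      abundance_metric = sample(c("cover", "biomass", "frequency"), 1L,
                                prob = c(0.6, 0.25, 0.15)),
      plot_size_m2 = stats::rlnorm(1, log(4), 1),
      duration_years = ny,
      management_coverage = stats::runif(1, 0, 100),
      climate_1 = clim[1], climate_2 = clim[2],
      climate_3 = clim[3], climate_4 = clim[4]
    )
    plots <- vector("list", np)
    for (p in seq_len(np)) {
      set.seed(child_seed(ds_seed, p))
      scale_p <- stats::rlnorm(1, 0, config$plot_scale_sd)
      dev_p <- stats::rlnorm(config$pool_size, 0, config$species_plot_sd)
      x <- simulate_plot_series(mu * scale_p * dev_p, config, ny)
      plots[[p]] <- data.frame(
        dataset_id = did,
        plot_id = sprintf("%s_P%03d", did, p),
        year = rep(seq_len(ny), times = config$pool_size),
        species_id = rep(sp_ids, each = ny),
        abundance = as.vector(x)
      )
    }
    rec_list[[d]] <- do.call(rbind, plots)
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  covariates <- do.call(rbind, cov_list)
  rownames(covariates) <- NULL
  list(records = records, covariates = covariates)
}

#' Simulate plot-level metric pairs with a planted correlation
#'
#' Draws `n_plots` bivariate standard-normal pairs with population
#' correlation `rho`, interpreted as (log diversity, log CV) values for the
#' plots of one dataset. Used to validate the per-dataset correlation stage
#' against a known truth.
#'
#' @param n_plots Number of plots (>= 2).
#' @param rho Target population correlation in \[-1, 1\].
#'
#' @return Data frame with columns `log_diversity` and `log_cv`.
#' @export
simulate_planted_correlation <- function(n_plots, rho) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (n_plots < 2) stop("n_plots must be >= 2", call. = FALSE)
  x <- stats::rnorm(n_plots)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_plots)
  data.frame(log_diversity = x, log_cv = y)
}
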