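# Per-plot population stability and richness metrics.
#
# Conventions, fixed so that independent oracles match bit-for-bit:
#  - absence years count as abundance 0 in mu, sigma and the detrended
#    variance for every retained species;
#  - sample SD uses the n-1 denominator;
#  - relative abundance p_i normalizes over retained species only, so WPCV is
#    a proper convex combination of the CVs actually computed;
#  - richness and turnover are computed on unfiltered data by default
#    (the occurrence filter exists to stabilize CVs, not richness).

#' Temporal statistics for one species' abundance series
#'
#' @param x Numeric abundance-per-year vector (absence years as 0), length
#'   >= 2, at least one positive value.
#' @return A list with `mu` (temporal mean), `sigma` (sample SD, n-1
#'   denominator), `cv` (`sigma/mu`) and `occurrence_fraction` (share of
#'   years with abundance > 0).
#' @export
#' @examples
#' species_temporal_stats(c(1, 2, 3)) # mu 2, sigma 1, cv 0.5
species_temporal_stats <- function(x) {
  if (length(x) < 2) stop("series must have >= 2 years", call. = FALSE)
  if (all(x == 0)) stop("all-zero series: statistics undefined", call. = FALSE)
  if (any(x < 0)) stop("abundances must be >= 0", call. = FALSE)
  mu <- mean(x)
  sigma <- stats::sd(x)
  list(mu = mu, sigma = sigma, cv = sigma / mu,
       occurrence_fraction = mean(x > 0))
}

#' Three-term local variance (detrended variance) of a series
#'
#' Detrends by squared second differences over consecutive year triplets:
#' \deqn{TTLV = \sum_{t=2}^{n-1} (x_{t-1} - 2 x_t + x_{t+1})^2 / (6 (n-2)).}
#' Second differences annihilate any affine trend, and the 6(n-2)
#' normalization makes TTLV unbiased for the noise variance of iid
#' fluctuations about a linear trend. The detrended CV is
#' \eqn{\sqrt{TTLV}/\mu}.
#'
#' @param x Numeric vector, length >= 3.
#' @return The detrended variance (scalar >= 0).
#' @export
#' @examples
#' ttlv(1:10)        # 0: linear trends are removed exactly
#' ttlv(c(0, 1, 0))  # (0 - 2 + 0)^2 / 6 = 2/3
ttlv <- function(x) {
  n <- length(x)
  if (n < 3) stop("three-term local variance needs >= 3 years", call. = FALSE)
  sum(diff(x, differences = 2)^2) / (6 * (n - 2))
}

#' Occurrence filter for a plot's species
#'
#' Species are retained when they occur (abundance > 0) in at least
#' `threshold` of the plot's sampled years; with the default 30% threshold, a
#' species seen 3 times in a 10-year plot is kept and one seen twice is not.
#' A species never observed is always dropped.
#'
#' @param mat Years-by-species abundance matrix for one plot.
#' @param threshold Occurrence fraction in \[0, 1\]; default 0.30.
#' @return Character vector of retained species (column names), possibly
#'   empty.
#' @export
occurrence_filter <- function(mat, threshold = 0.3) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (nrow(mat) < 1) stop("plot must have >= 1 sampled year", call. = FALSE)
  occ <- colMeans(mat > 0)
  colnames(mat)[occ > 0 & occ >= threshold]
}

#' Classify retained species into dominant / subordinate / rare
#'
#' The single most abundant species (largest relative mean abundance) is
#' dominant; of the remainder, species with relative abundance below
#' `rare_cutoff` are rare and all others subordinate. The dominant label is
#' assigned first and never downgraded. Ties for dominance break to the
#' lexicographically smallest species identifier, so labels do not depend on
#' input order.
#'
#' @param p Named numeric vector of relative mean abundances (sums to 1 over
#'   retained species).
#' @param rare_cutoff Relative-abundance cutoff below which non-dominant
#'   species are rare; default 0.05.
#' @return Character vector (same names as `p`) with values `"dominant"`,
#'   `"subordinate"` or `"rare"`; zero-length for empty input.
#' @export
classify_groups <- function(p, rare_cutoff = 0.05) {
  if (rare_cutoff <= 0 || rare_cutoff >= 1)
    stop("rare_cutoff must lie in (0, 1)", call. = FALSE)
  if (length(p) == 0) return(character(0))
  stopifnot(!is.null(names(p)))
  dom <- names(p)[order(-p, names(p))[1]]
  g <- ifelse(p < rare_cutoff, "rare", "subordinate")
  names(g) <- names(p)
  g[dom] <- "dominant"
  g
}

#' Average richness, cumulative richness and temporal turnover
#'
#' Average richness is the mean annual number of species present; cumulative
#' richness the number of distinct species ever present; turnover their ratio
#' (multiplicative temporal beta diversity, >= 1, equal to 1 exactly when no
#' species recorded in the plot is ever absent).
#'
#' @param mat Years-by-species abundance matrix for one plot.
#' @return List with `average_richness`, `cumulative_richness`, `turnover`.
#' @export
richness_and_turnover <- function(mat) {
  if (nrow(mat) < 1) stop("plot must have >= 1 sampled year", call. = FALSE)
  present <- mat > 0
  cumulative <- sum(colSums(present) > 0)
  if (cumulative == 0)
    stop("no species ever present: richness undefined", call. = FALSE)
  average <- mean(rowSums(present))
  list(average_richness = average, cumulative_richness = cumulative,
       turnover = cumulative / average)
}

#' Per-plot diversity and stability metrics
#'
#' Applies the occurrence filter, computes each retained species' temporal
#' statistics (absence years as zeros), and aggregates them into the plot's
#' unweighted and weighted mean population CVs
#' \deqn{UPCV = \frac{1}{S}\sum_i \frac{\sigma_i}{\mu_i}, \qquad
#'       WPCV = \sum_i \frac{\sigma_i}{\mu_i} p_i,}
#' their detrended variants (CVs from [ttlv()]), group-level unweighted CVs
#' and mean population sizes for dominant / subordinate / rare species, and
#' the richness and turnover measures. Richness is computed on all species by
#' default; set `richness_filtered = TRUE` to restrict it to retained
#' species.
#'
#' @param mat Years-by-species abundance matrix for one plot (>= 2 years).
#' @param threshold Occurrence-filter threshold (default 0.30).
#' @param rare_cutoff Rare-species relative-abundance cutoff (default 0.05).
#' @param richness_filtered Compute richness/turnover on retained species
#'   only? Default `FALSE`.
#' @return One-row data frame with columns `n_years`, `average_richness`,
#'   `cumulative_richness`, `turnover`, `n_retained`, `upcv`, `wpcv`,
#'   `upcv_detrended`, `wpcv_detrended`, `upcv_d`, `upcv_s`, `upcv_r`,
#'   `popsize_d`, `popsize_s`, `popsize_r`. Stability columns are `NA` when
#'   no species survives the filter (the plot is still reported for
#'   richness); group columns are `NA` for empty groups.
#' @export
#' @examples
#' m <- cbind(a = c(3, 2, 4), b = c(1, 1, 1))
#' compute_plot_metrics(m)
compute_plot_metrics <- function(mat, threshold = 0.3, rare_cutoff = 0.05,
                                 richness_filtered = FALSE) {
  if (nrow(mat) < 2) stop("plot must have >= 2 sampled years", call. = FALSE)
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  rich <- richness_and_turnover(mat)
  retained <- occurrence_filter(mat, threshold)
  out <- data.frame(
    n_years = nrow(mat),
    average_richness = rich$average_richness,
    cumulative_richness = rich$cumulative_richness,
    turnover = rich$turnover,
    n_retained = length(retained),
    upcv = NA_real_, wpcv = NA_real_,
    upcv_detrended = NA_real_, wpcv_detrended = NA_real_,
    upcv_d = NA_real_, upcv_s = NA_real_, upcv_r = NA_real_,
    popsize_d = NA_real_, popsize_s = NA_real_, popsize_r = NA_real_
  )
  if (length(retained) == 0) return(out)
  if (richness_filtered) {
    rich <- richness_and_turnover(mat[, retained, drop = FALSE])
    out$average_richness <- rich$average_richness
    out$cumulative_richness <- rich$cumulative_richness
    out$turnover <- rich$turnover
  }
  sub <- mat[, retained, drop = FALSE]
  mu <- colMeans(sub)
  sigma <- apply(sub, 2, stats::sd)
  cv <- sigma / mu
  p <- mu / sum(mu)
  out$upcv <- mean(cv)
  out$wpcv <- sum(cv * p)
  if (nrow(sub) >= 3) {
    cv_det <- sqrt(apply(sub, 2, ttlv)) / mu
    out$upcv_detrended <- mean(cv_det)
    out$wpcv_detrended <- sum(cv_det * p)
  }
  g <- classify_groups(p, rare_cutoff)
  for (grp in c("dominant", "subordinate", "rare")) {
    suf <- substr(grp, 1, 1)
    idx <- g == grp
    if (any(idx)) {
      out[[paste0("upcv_", suf)]] <- mean(cv[idx])
      out[[paste0("popsize_", suf)]] <- mean(mu[idx])
    }
  }
  out
}

# Long records for one plot -> years x species abundance matrix.
# Sampled years are the years appearing in the records; species-year cells
# not present are zeros.
plot_matrix <- function(year, species_id, abundance) {
  years <- sort(unique(year))
  sps <- sort(unique(as.character(species_id)))
  m <- matrix(0, length(years), length(sps),
              dimnames = list(years, sps))
  m[cbind(match(year, years), match(as.character(species_id), sps))] <-
    abundance
  m
}

#' Plot-level metrics for a whole abundance table
#'
#' Applies [compute_plot_metrics()] to every (dataset, plot) in a long-format
#' abundance table.
#'
#' @param records Data frame with columns `dataset_id`, `plot_id`, `year`,
#'   `species_id`, `abundance` (absences as explicit zeros or omitted rows).
#' @inheritParams compute_plot_metrics
#' @return Data frame with one row per plot: `dataset_id`, `plot_id`, and the
#'   [compute_plot_metrics()] columns.
#' @export
plot_metrics <- function(records, threshold = 0.3, rare_cutoff = 0.05,
                         richness_filtered = FALSE) {
  validate_records(records)
  key <- paste(records$dataset_id, records$plot_id, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    m <- plot_matrix(records$year[i], records$species_id[i],
                     records$abundance[i])
    pm <- compute_plot_metrics(m, threshold, rare_cutoff, richness_filtered)
    cbind(data.frame(dataset_id = records$dataset_id[i[1]],
                     plot_id = records$plot_id[i[1]]), pm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$dataset_id, out$plot_id), , drop = FALSE]
}
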