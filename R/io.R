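# Readers/writers for the pipeline's plain-CSV tables.

validate_records <- function(records) {
  required <- c("dataset_id", "plot_id", "year", "species_id", "abundance")
  miss <- setdiff(required, names(records))
  if (length(miss))
    stop("records table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  neg <- which(records$abundance < 0)
  if (length(neg))
    stop("negative abundance at row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  key <- paste(records$dataset_id, records$plot_id, records$year,
               records$species_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (dataset, plot, year, species) record(s), first at row ",
         which(duplicated(key))[1], call. = FALSE)
  invisible(records)
}

#' Read a long-format abundance table
#'
#' Expects a delimited text file with columns `dataset_id`, `plot_id`,
#' `year`, `species_id`, `abundance`. Missing species-year cells mean
#' abundance 0; duplicate records and negative abundances are errors.
#'
#' @param path File path (CSV).
#' @return Validated data frame.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

#' Write a long-format abundance table
#'
#' @param records Abundance table (see [read_records()]).
#' @param path Output CSV path.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-dataset covariate table
#'
#' @param path File path (CSV with at least a `dataset_id` column).
#' @return Data frame.
#' @export
read_covariates <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"dataset_id" %in% names(cov))
    stop("covariate table is missing column: dataset_id", call. = FALSE)
  cov
}

# FNV-1a 32-bit hash of a string, as 8 hex digits; used to stamp outputs
# with the configuration they came from.
fnv1a32 <- function(s) {
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
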