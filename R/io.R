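#' Read an environmental time series
#'
#' Stream temperature or discharge records, one row per measurement. Multiple
#' sites may share a file; series are kept separate per site. Timestamps must
#' be strictly increasing within a site and each site needs at least two
#' values.
#'
#' @param path CSV path with columns `site`, `timestamp`, `value` (or mapped
#'   via `dialect`).
#' @param variable `"temperature"` (degrees C) or `"discharge"` (m^3/s).
#' @param dialect Optional named mapping of canonical to file column names,
#'   as in [read_community_long()].
#' @return An `env_series` tibble with columns `site`, `variable`,
#'   `timestamp`, `value`.
#' @export
read_env_series <- function(path, variable = c("temperature", "discharge"),
                            dialect = NULL) {
  variable <- match.arg(variable)
  df <- read_mapped_csv(path, dialect, required = c("site", "timestamp", "value"))
  as_env_series(df, variable)
}

#' @rdname read_env_series
#' @param df Data frame with columns `site`, `timestamp`, `value`, and
#'   optionally `variable` (used when the `variable` argument is `NULL`).
#' @export
as_env_series <- function(df, variable = NULL) {
  vars <- if (is.null(variable)) as.character(df$variable) else {
    rep(match.arg(variable, c("temperature", "discharge")), nrow(df))
  }
  bad <- setdiff(unique(vars), c("temperature", "discharge"))
  if (length(bad) > 0) {
    ss_abort(sprintf("Unknown environmental variable(s): %s.",
                     paste(bad, collapse = ", ")),
             "streamsync_validation_error")
  }
  out <- tibble::tibble(site = as.character(df$site),
                        variable = vars,
                        timestamp = as.double(df$timestamp),
                        value = as.double(df$value))
  key <- paste(out$site, out$variable)
  for (k in unique(key)) {
    ts <- out$timestamp[key == k]
    if (length(ts) < 2) {
      ss_abort(sprintf("Series `%s` has fewer than 2 values.", k),
               "streamsync_insufficient_data_error")
    }
    if (is.unsorted(ts, strictly = TRUE)) {
      ss_abort(sprintf("Timestamps for series `%s` are not strictly increasing.", k),
               "streamsync_validation_error")
    }
  }
  class(out) <- c("env_series", class(out))
  out
}

#' Read a taxon-to-functional-feeding-group assignment table
#'
#' Each taxon maps to exactly one of the five stream-macroinvertebrate
#' functional feeding groups: filterer, gatherer, predator, scraper, shredder.
#'
#' @param path CSV path with columns `taxon`, `group`.
#' @param dialect Optional column mapping.
#' @return An `ffg_table` tibble with columns `taxon`, `group` (factor with
#'   the five levels).
#' @export
read_ffg_table <- function(path, dialect = NULL) {
  df <- read_mapped_csv(path, dialect, required = c("taxon", "group"))
  as_ffg_table(df)
}

#' @rdname read_ffg_table
#' @param df Data frame with columns `taxon`, `group`.
#' @export
as_ffg_table <- function(df) {
  out <- tibble::tibble(taxon = as.character(df$taxon),
                        group = as.character(df$group))
  bad <- setdiff(unique(out$group), ffg_levels())
  if (length(bad) > 0) {
    ss_abort(sprintf(
      "Unknown functional feeding group label(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(ffg_levels(), collapse = ", ")),
      "streamsync_validation_error")
  }
  if (anyDuplicated(out$taxon)) {
    dup <- unique(out$taxon[duplicated(out$taxon)])
    ss_abort(sprintf("Taxa assigned to more than one group: %s.",
                     paste(head(dup, 5), collapse = ", ")),
             "streamsync_validation_error")
  }
  out$group <- factor(out$group, levels = ffg_levels())
  class(out) <- c("ffg_table", class(out))
  out
}

#' Read site coordinates
#'
#' @param path CSV path with columns `site`, `lat`, `lon`.
#' @param dialect Optional column mapping.
#' @return A `site_coords` tibble.
#' @export
read_site_coords <- function(path, dialect = NULL) {
  df <- read_mapped_csv(path, dialect, required = c("site", "lat", "lon"))
  as_site_coords(df)
}

#' @rdname read_site_coords
#' @param df Data frame with columns `site`, `lat`, `lon`.
#' @export
as_site_coords <- function(df) {
  out <- tibble::tibble(site = as.character(df$site),
                        lat = as.double(df$lat), lon = as.double(df$lon))
  if (anyDuplicated(out$site)) {
    ss_abort("Duplicate site identifiers in coordinate table.",
             "streamsync_validation_error")
  }
  bad <- which(abs(out$lat) > 90 | abs(out$lon) > 180 |
                 !is.finite(out$lat) | !is.finite(out$lon))
  if (length(bad) > 0) {
    ss_abort(sprintf("Coordinates out of range at row(s): %s (|lat| <= 90, |lon| <= 180).",
                     paste(bad, collapse = ", ")),
             "streamsync_validation_error")
  }
  class(out) <- c("site_coords", class(out))
  out
}

#' Write and re-read the per-site summary table
#'
#' One row per site with the columns of the site-level results table:
#' coordinates, taxonomic richness `S`, temperature and discharge variability
#' (SD of the full series), mean temporal turnover, community synchrony `phi`
#' and its Monte Carlo p-value.
#'
#' @param summaries A `site_summary` tibble (rows from [build_site_summary()]).
#' @param path Output CSV path.
#' @return `path` invisibly (`write_site_summary`); a `site_summary` tibble
#'   (`read_site_summary`).
#' @export
write_site_summary <- function(summaries, path) {
  cols <- c("site", "lat", "lon", "S", "temp_sd", "turnover_mean",
            "discharge_sd", "phi", "p_value")
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    ss_abort("`summaries` must be a non-empty data frame of site summaries.",
             "streamsync_parameter_error")
  }
  missing <- setdiff(cols, names(summaries))
  if (length(missing) > 0) {
    ss_abort(sprintf("Site summary is missing column(s): %s.",
                     paste(missing, collapse = ", ")),
             "streamsync_format_error")
  }
  readr::write_csv(as.data.frame(summaries)[cols], path)
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_site_summary <- function(path) {
  df <- read_mapped_csv(path, NULL,
                        required = c("site", "lat", "lon", "S", "temp_sd",
                                     "turnover_mean", "discharge_sd", "phi",
                                     "p_value"))
  out <- tibble::as_tibble(df)
  out$site <- as.character(out$site)
  class(out) <- c("site_summary", class(out))
  out
}
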