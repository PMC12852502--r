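#' Read a long-format community abundance table
#'
#' Ingests sampling-event records of taxon densities into a validated
#' community table: one row per (site, year, sampling event, taxon) with a
#' non-negative density (individuals per unit area, already normalized for
#' sampling effort upstream). Column names in the file are adapted through
#' `dialect`, so exports with field-program-specific headers can be read
#' without editing the file.
#'
#' Duplicate (site, year, event, taxon) rows are an error rather than being
#' summed: aggregation across taxonomic ranks must be done explicitly before
#' ingestion, and silent summation would hide taxonomy mistakes.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping the canonical column names
#'   `site`, `year`, `event`, `taxon`, `density` to the names used in the
#'   file. Defaults to the identity mapping.
#' @return A tibble of class `community_table` with columns `site`, `year`,
#'   `event`, `taxon`, `density`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   site = "S1", year = c(2020, 2020, 2021, 2021),
#'   event = 1L, taxon = c("Baetis", "Simulium", "Baetis", "Simulium"),
#'   density = c(10, 5, 12, 4)), f)
#' read_community_long(f)
#' @seealso [to_site_matrix()], [write_community()]
#' @export
read_community_long <- function(path, dialect = NULL) {
  df <- read_mapped_csv(path, dialect,
                        required = c("site", "year", "event", "taxon", "density"))
  as_community_table(df)
}

#' Validate a data frame as a community table
#'
#' @param df Data frame with columns `site`, `year`, `event`, `taxon`,
#'   `density`.
#' @return A `community_table` tibble.
#' @export
as_community_table <- function(df) {
  required <- c("site", "year", "event", "taxon", "density")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ss_abort(sprintf("Community table is missing column(s): %s.",
                     paste(missing, collapse = ", ")),
             "streamsync_format_error")
  }
  out <- tibble::as_tibble(df[required])
  out$site <- as.character(out$site)
  out$year <- as.integer(out$year)
  out$event <- as.integer(out$event)
  out$taxon <- as.character(out$taxon)
  out$density <- as.double(out$density)

  bad <- which(!is.finite(out$density) | out$density < 0)
  if (length(bad) > 0) {
    ss_abort(sprintf("Negative or non-finite density at row(s): %s.",
                     paste(head(bad, 5), collapse = ", ")),
             "streamsync_validation_error")
  }
  dup <- duplicated(out[c("site", "year", "event", "taxon")])
  if (any(dup)) {
    ss_abort(sprintf(
      "Duplicate (site, year, event, taxon) rows at: %s. Aggregate taxa explicitly before ingestion.",
      paste(head(which(dup), 5), collapse = ", ")),
      "streamsync_validation_error")
  }
  class(out) <- c("community_table", class(out))
  out
}

#' Write a community table to CSV
#'
#' Inverse of [read_community_long()]: `read_community_long(write_community(x, f))`
#' returns a table identical to `x` up to row order.
#'
#' @param table A `community_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_community <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  readr::write_csv(as.data.frame(table), path)
  invisible(path)
}

# Shared reader: rename file columns to canonical names through a dialect map.
read_mapped_csv <- function(path, dialect, required) {
  if (!file.exists(path)) {
    ss_abort(sprintf("File not found: %s", path), "streamsync_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      ss_abort("`dialect` must be a named character vector (canonical = file column).",
               "streamsync_parameter_error")
    }
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(df)) {
        ss_abort(sprintf("Column `%s` (mapped to `%s`) not found in %s.",
                         file_col, canon, path),
                 "streamsync_format_error")
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ss_abort(sprintf("%s is missing required column(s): %s.",
                     path, paste(missing, collapse = ", ")),
             "streamsync_format_error")
  }
  df
}

#' Sites available in a community table
#' @param table A `community_table`.
#' @return Character vector of site identifiers, sorted.
#' @export
community_sites <- function(table) sort(unique(table$site))
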