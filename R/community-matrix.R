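#' Annualize one site's records into a years-by-taxa density matrix
#'
#' Sampling occurs several times per year over short windows, so densities are
#' averaged across sampling events within each year to give one annual density
#' per taxon: the unit on which community synchrony is computed. A taxon not
#' recorded in a sampled event is an observed zero for that event (presence
#' records imply absence elsewhere in the same event), so the annual value is
#' the sum of recorded densities divided by the number of events sampled that
#' year. Taxa never observed at the site (all-zero columns) are dropped;
#' remaining taxa are ordered lexicographically so the matrix is independent
#' of file row order.
#'
#' @param table A `community_table`.
#' @param site Site identifier present in `table`.
#' @return A `community_matrix`: list with `site_id`, `years` (strictly
#'   increasing integer vector, length T >= 2), `taxa` (sorted character
#'   vector), and `X` (T x N matrix of annual mean densities).
#' @examples
#' tbl <- as_community_table(tibble::tibble(
#'   site = "S1", year = rep(c(2020, 2021), each = 2), event = c(1, 2, 1, 2),
#'   taxon = "Baetis", density = c(1, 3, 2, 6)))
#' to_site_matrix(tbl, "S1")$X
#' @export
to_site_matrix <- function(table, site) {
  stopifnot(inherits(table, "community_table"))
  rows <- table[table$site == site, , drop = FALSE]
  if (nrow(rows) == 0) {
    ss_abort(sprintf("Site `%s` not present in community table.", site),
             "streamsync_lookup_error")
  }
  years <- sort(unique(rows$year))
  if (length(years) < 2) {
    ss_abort(sprintf("Site `%s` has a single sampled year; >= 2 are required.", site),
             "streamsync_insufficient_data_error")
  }
  # events sampled per year at this site (any taxon recorded counts the event)
  n_events <- vapply(years, function(y) {
    length(unique(rows$event[rows$year == y]))
  }, integer(1))

  taxa <- sort(unique(rows$taxon))
  X <- matrix(0, nrow = length(years), ncol = length(taxa),
              dimnames = list(as.character(years), taxa))
  agg <- dplyr::summarise(
    dplyr::group_by(rows, .data$year, .data$taxon),
    total = sum(.data$density), .groups = "drop")
  X[cbind(match(agg$year, years), match(agg$taxon, taxa))] <- agg$total
  X <- sweep(X, 1, n_events, "/")

  keep <- colSums(X) > 0
  X <- X[, keep, drop = FALSE]
  new_community_matrix(site, years, colnames(X), X)
}

new_community_matrix <- function(site_id, years, taxa, X) {
  if (ncol(X) < 1) {
    ss_abort(sprintf("Site `%s` has no taxon with a positive density.", site_id),
             "streamsync_validation_error")
  }
  structure(
    list(site_id = site_id, years = as.integer(years),
         taxa = as.character(taxa), X = X),
    class = "community_matrix")
}

#' Construct a community matrix from a plain matrix
#'
#' Mostly useful in tests and simulations; `X` must be non-negative with no
#' all-zero column.
#'
#' @param X Numeric T x N matrix (T years, N taxa).
#' @param site_id Site label.
#' @param years Integer vector of years (default `1:T`).
#' @param taxa Character vector of taxon labels (default `t01`, `t02`, ...).
#' @return A `community_matrix`.
#' @export
community_matrix <- function(X, site_id = "site", years = NULL, taxa = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(X < 0)) {
    ss_abort("Community matrix entries must be finite and non-negative.",
             "streamsync_validation_error")
  }
  years <- years %||% seq_len(nrow(X))
  if (is.unsorted(years, strictly = TRUE)) {
    ss_abort("`years` must be strictly increasing.", "streamsync_validation_error")
  }
  if (nrow(X) < 2) {
    ss_abort("A community matrix needs >= 2 years.",
             "streamsync_insufficient_data_error")
  }
  taxa <- taxa %||% colnames(X) %||% sprintf("t%02d", seq_len(ncol(X)))
  if (any(colSums(X) == 0)) {
    ss_abort("All-zero taxon columns are not allowed; drop them first.",
             "streamsync_validation_error")
  }
  dimnames(X) <- list(as.character(years), taxa)
  new_community_matrix(site_id, years, taxa, X)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> site %s: %d years (%d-%d) x %d taxa\n",
              x$site_id, length(x$years), min(x$years), max(x$years),
              length(x$taxa)))
  invisible(x)
}

#' @rdname to_site_matrix
#' @param x A `community_matrix`.
#' @param ... Unused.
#' @method tidy community_matrix
#' @export
tidy.community_matrix <- function(x, ...) {
  tibble::tibble(
    site = x$site_id,
    year = rep(x$years, times = length(x$taxa)),
    taxon = rep(x$taxa, each = length(x$years)),
    density = as.vector(x$X))
}
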