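#' Temporal species turnover between consecutive years
#'
#' For each consecutive pair of sampled years, the proportion of taxa gained
#' or lost relative to the richness of the union of the two annual
#' assemblages: `(gains + losses) / |union|`. Presence in a year means a
#' positive annual density in the annualized matrix. Identical assemblages
#' give 0, complete replacement gives 1, and turnover is symmetric in the two
#' years of a pair.
#'
#' @param matrix A `community_matrix` with at least 2 years.
#' @return A `turnover_result` tibble with columns `site`, `year_from`,
#'   `year_to`, `gains`, `losses`, `union_richness`, `turnover`, plus a
#'   `mean_turnover` attribute (arithmetic mean of the per-interval values).
#' @export
temporal_turnover <- function(matrix) {
  m <- coerce_community_matrix(matrix)
  P <- m$X > 0
  Tn <- nrow(P)
  rows <- purrr::map(seq_len(Tn - 1), function(t) {
    a <- P[t, ]; b <- P[t + 1, ]
    gains <- sum(b & !a)
    losses <- sum(a & !b)
    union_n <- sum(a | b)
    tibble::tibble(site = m$site_id,
                   year_from = m$years[t], year_to = m$years[t + 1],
                   gains = gains, losses = losses, union_richness = union_n,
                   turnover = (gains + losses) / union_n)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_turnover") <- mean(out$turnover)
  class(out) <- c("turnover_result", class(out))
  out
}

#' @rdname temporal_turnover
#' @param x A `turnover_result`.
#' @return `mean_turnover()`: the mean per-interval turnover, a scalar in
#'   `[0, 1]`.
#' @export
mean_turnover <- function(x) {
  stopifnot(inherits(x, "turnover_result"))
  attr(x, "mean_turnover")
}

#' Taxonomic richness of a site
#'
#' Number of taxa ever observed at the site, i.e. the column count of the
#' annualized matrix (all-zero columns are already dropped at construction).
#'
#' @param matrix A `community_matrix`.
#' @return Integer richness S.
#' @export
richness <- function(matrix) {
  length(coerce_community_matrix(matrix)$taxa)
}

#' Simpson diversity (complement form)
#'
#' `1 - sum(p_i^2)` with `p_i` the relative abundances: the probability that
#' two randomly drawn individuals belong to different taxa. Computed through
#' \pkg{vegan}'s `"simpson"` index. Ranges from 0 (single taxon) to
#' `1 - 1/N` (even community of N taxa).
#'
#' @param abundances Non-negative numeric vector with at least one positive
#'   entry.
#' @return Scalar diversity in `[0, 1)`.
#' @export
simpson_diversity <- function(abundances) {
  if (!is.numeric(abundances) || any(!is.finite(abundances)) ||
      any(abundances < 0)) {
    ss_abort("`abundances` must be finite and non-negative.",
             "streamsync_validation_error")
  }
  if (sum(abundances) == 0) {
    ss_abort("Simpson diversity is undefined for an all-zero community.",
             "streamsync_undefined_error")
  }
  unname(vegan::diversity(matrix(abundances, nrow = 1), index = "simpson"))
}

#' Environmental variability
#'
#' Variability of a stream temperature or discharge record, quantified as the
#' sample standard deviation (divisor n - 1) of the full time series at its
#' native measurement resolution — no resampling to a common grid. Given an
#' `env_series` covering several sites or variables, one value per
#' site-variable pair is returned.
#'
#' @param series An `env_series` tibble, or a bare numeric vector (>= 2
#'   values).
#' @return For a vector: a scalar SD in the series' units. For an
#'   `env_series`: a tibble with columns `site`, `variable`, `sd`, `n`.
#' @export
env_variability <- function(series) {
  if (is.numeric(series)) {
    if (length(series) < 2) {
      ss_abort("At least 2 values are needed for a standard deviation.",
               "streamsync_insufficient_data_error")
    }
    return(sd(series))
  }
  stopifnot(inherits(series, "env_series"))
  dplyr::summarise(dplyr::group_by(series, .data$site, .data$variable),
                   sd = sd(.data$value), n = dplyr::n(), .groups = "drop")
}

#' Assemble the one-row site summary
#'
#' Combines the site's annualized community matrix, environmental series,
#' coordinates and synchrony test into the row format of the site-level
#' results table: richness, temperature and discharge SD, mean turnover, phi
#' and its p-value.
#'
#' @param matrix The site's `community_matrix`.
#' @param temp Temperature `env_series` containing the site.
#' @param discharge Discharge `env_series` containing the site.
#' @param coords `site_coords` containing the site.
#' @param synchrony A `synchrony_result` for the same site (from
#'   [community_null_test()]).
#' @return A one-row `site_summary` tibble.
#' @export
build_site_summary <- function(matrix, temp, discharge, coords, synchrony) {
  m <- coerce_community_matrix(matrix)
  sid <- m$site_id
  if (!identical(synchrony$site_id, sid)) {
    ss_abort(sprintf("Synchrony result is for site `%s`, matrix for `%s`.",
                     synchrony$site_id, sid), "streamsync_consistency_error")
  }
  pick_env <- function(es, what) {
    stopifnot(inherits(es, "env_series"))
    v <- es$value[es$site == sid & es$variable == what]
    if (length(v) < 2) {
      ss_abort(sprintf("No %s series for site `%s`.", what, sid),
               "streamsync_consistency_error")
    }
    sd(v)
  }
  crow <- coords[coords$site == sid, , drop = FALSE]
  if (nrow(crow) != 1) {
    ss_abort(sprintf("No coordinates for site `%s`.", sid),
             "streamsync_consistency_error")
  }
  out <- tibble::tibble(
    site = sid, lat = crow$lat, lon = crow$lon,
    S = richness(m),
    temp_sd = pick_env(temp, "temperature"),
    turnover_mean = mean_turnover(temporal_turnover(m)),
    discharge_sd = pick_env(discharge, "discharge"),
    phi = synchrony$phi, p_value = synchrony$p_value)
  class(out) <- c("site_summary", class(out))
  out
}
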