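#' Configuration for the synthetic multi-site study generator
#'
#' Defines a NEON-shaped study: `n_sites` wadeable-stream sites sampled
#' `events_per_year` times a year for `n_years` years, each hosting a
#' community drawn from a shared genus pool with functional-feeding-group
#' labels. Cross-taxon synchrony is controlled on the log-density scale by a
#' factor model — a site-wide driver shared by all taxa plus one driver per
#' feeding group — whose loadings are chosen so the pairwise log-density
#' correlation is exactly `rho_within` inside a group and `rho_between`
#' across groups (`rho_between <= rho_within`). Year-to-year presence
#' turnover is imposed by masking latent abundances to zero with per-year
#' extinction/colonization probability `turnover_rate`, which leaves the
#' correlation structure of persisting taxa intact. Event-level observation
#' noise is lognormal with log-scale SD `event_noise_sd` (mean-one, so
#' annualization is unbiased).
#'
#' Defaults emulate the published study conditions: 18 sites x 8 years x 3
#' sampling events, 100-230 genera per site, temperature-variability targets
#' spanning 1-18 degrees C and discharge-variability targets 0.002-0.44
#' m^3/s, gatherer-dominated group weights, and correlation levels that put
#' site synchrony in the 0.1-0.3 band typical of these communities.
#'
#' @param n_sites Number of sites (default 18).
#' @param n_years Sampled years per site (default 8).
#' @param events_per_year Sampling events per year (default 3).
#' @param n_taxa_range Integer interval for per-site richness (default
#'   `c(100, 230)`); the shared pool has `max(n_taxa_range)` genera.
#' @param ffg_weights Named 5-vector of group proportions summing to 1.
#' @param rho_within Pairwise log-density correlation within a feeding group,
#'   in `[0, 1]` (default 0.25).
#' @param rho_between Correlation across groups, `<= rho_within`
#'   (default 0.15).
#' @param env_loading Named 5-vector of per-group loadings on a site-level
#'   environmental driver added to the latent log-densities (default all 0,
#'   which keeps the correlation targets exact).
#' @param turnover_rate Per-year extinction/colonization probability in
#'   `[0, 1]` (default 0.2).
#' @param event_noise_sd Log-scale SD of event-level observation noise
#'   (default 0.5).
#' @param temp_sd_range,discharge_sd_range Intervals from which each site's
#'   target series SD is drawn (degrees C; m^3/s).
#' @param density_log_mean,density_log_sd Mean and SD of per-taxon mean
#'   log-densities (abundance heterogeneity).
#' @param series_log_sd Temporal SD of the latent log-density series
#'   (default 0.6).
#' @param start_year First calendar year (default 2014).
#' @param seed Master seed; every draw derives from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 18, n_years = 8, events_per_year = 3,
                             n_taxa_range = c(100, 230),
                             ffg_weights = c(filterer = 0.10, gatherer = 0.40,
                                             predator = 0.20, scraper = 0.15,
                                             shredder = 0.15),
                             rho_within = 0.25, rho_between = 0.15,
                             env_loading = c(filterer = 0, gatherer = 0,
                                             predator = 0, scraper = 0,
                                             shredder = 0),
                             turnover_rate = 0.2, event_noise_sd = 0.5,
                             temp_sd_range = c(1, 18),
                             discharge_sd_range = c(0.002, 0.44),
                             density_log_mean = log(50), density_log_sd = 0.75,
                             series_log_sd = 0.6,
                             start_year = 2014, seed = 1L) {
  cfg <- list(n_sites = stopifnot_scalar_count(n_sites, "n_sites"),
              n_years = stopifnot_scalar_count(n_years, "n_years", min = 2L),
              events_per_year = stopifnot_scalar_count(events_per_year,
                                                       "events_per_year"),
              n_taxa_range = as.integer(n_taxa_range),
              ffg_weights = ffg_weights, rho_within = rho_within,
              rho_between = rho_between, env_loading = env_loading,
              turnover_rate = turnover_rate, event_noise_sd = event_noise_sd,
              temp_sd_range = as.double(temp_sd_range),
              discharge_sd_range = as.double(discharge_sd_range),
              density_log_mean = density_log_mean,
              density_log_sd = density_log_sd,
              series_log_sd = series_log_sd,
              start_year = as.integer(start_year),
              seed = as.integer(seed))
  cfg_err <- function(msg) ss_abort(msg, "streamsync_config_error")
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0)
      cfg_err(sprintf("`%s` must be a non-negative interval c(min, max) with min <= max.", nm))
  }
  chk_range(cfg$n_taxa_range, "n_taxa_range")
  if (cfg$n_taxa_range[1] < 1) cfg_err("`n_taxa_range` minimum must be >= 1.")
  chk_range(cfg$temp_sd_range, "temp_sd_range")
  chk_range(cfg$discharge_sd_range, "discharge_sd_range")
  for (nm in c("ffg_weights", "env_loading")) {
    v <- cfg[[nm]]
    if (length(v) != 5 || !setequal(names(v), ffg_levels()))
      cfg_err(sprintf("`%s` must be a 5-vector named %s.", nm,
                      paste(ffg_levels(), collapse = ", ")))
    cfg[[nm]] <- v[ffg_levels()]
  }
  if (abs(sum(cfg$ffg_weights) - 1) > 1e-8 || any(cfg$ffg_weights < 0))
    cfg_err("`ffg_weights` must be non-negative and sum to 1.")
  for (nm in c("rho_within", "rho_between", "turnover_rate")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      cfg_err(sprintf("`%s` must be a single value in [0, 1].", nm))
  }
  if (cfg$rho_between > cfg$rho_within)
    cfg_err("`rho_between` must not exceed `rho_within`.")
  if (cfg$event_noise_sd < 0 || cfg$series_log_sd < 0 || cfg$density_log_sd < 0)
    cfg_err("Noise SDs must be non-negative.")
  structure(cfg, class = "synthetic_config")
}

#' Site identifiers of a synthetic study
#' @param config A `synthetic_config`.
#' @return Character vector `S01`, `S02`, ...
#' @export
synthetic_sites <- function(config) {
  sprintf("S%02d", seq_len(config$n_sites))
}

# Derived substream seeds; fixed draw order makes every generated object a
# pure function of the config.
config_seeds <- function(config) {
  s <- substream_seeds(config$seed, 2L + 2L * config$n_sites)
  list(pool = s[1], coords = s[2],
       site = s[2 + seq_len(config$n_sites)],
       env = s[2 + config$n_sites + seq_len(config$n_sites)])
}

# Shared genus pool with feeding-group labels; identical for every site so
# genera cross sites (needed by the crossed random-effects model).
taxon_pool <- function(config) {
  n_pool <- config$n_taxa_range[2]
  withr::with_seed(config_seeds(config)$pool, {
    groups <- sample(ffg_levels(), n_pool, replace = TRUE,
                     prob = config$ffg_weights)
    as_ffg_table(tibble::tibble(taxon = sprintf("G%03d", seq_len(n_pool)),
                                group = groups))
  })
}

site_index <- function(config, site) {
  i <- match(site, synthetic_sites(config))
  if (is.na(i)) {
    ss_abort(sprintf("Unknown synthetic site `%s`.", site),
             "streamsync_lookup_error")
  }
  i
}

#' Generate one site's environmental series
#'
#' Weekly temperature and discharge series spanning the study years, each
#' calibrated to a per-site target SD drawn from the configured range.
#' Temperature is a seasonal sinusoid plus Gaussian noise (80% of the target
#' variance in the seasonal cycle, 20% in noise). Discharge is lognormal base
#' flow with occasional multiplicative spike events (flashy high-flow days),
#' rescaled so the sample SD equals the target exactly.
#'
#' @param config A `synthetic_config`.
#' @param site Site id from [synthetic_sites()].
#' @return An `env_series` tibble with both variables for the site;
#'   timestamps are decimal years.
#' @export
generate_env <- function(config, site) {
  stopifnot(inherits(config, "synthetic_config"))
  i <- site_index(config, site)
  n <- config$n_years * 52L
  t_dec <- config$start_year + (seq_len(n) - 1) / 52
  withr::with_seed(config_seeds(config)$env[i], {
    s_temp <- runif(1, config$temp_sd_range[1], config$temp_sd_range[2])
    amp <- s_temp * sqrt(2 * 0.8)
    temp <- 10 + amp * sinpi(2 * (t_dec - config$start_year)) +
      rnorm(n, 0, s_temp * sqrt(0.2))

    s_dis <- runif(1, config$discharge_sd_range[1], config$discharge_sd_range[2])
    q_raw <- exp(rnorm(n, 0, 0.7)) * exp(2 * rbinom(n, 1, 0.05))
    q <- q_raw * (s_dis / sd(q_raw))

    as_env_series(tibble::tibble(
      site = site,
      variable = rep(c("temperature", "discharge"), each = n),
      timestamp = c(t_dec, t_dec),
      value = c(temp, q)))
  })
}

#' Generate one site's community table
#'
#' Draws the site's richness and genus identities from the shared pool, then
#' simulates annual latent log-densities from the compound-symmetry factor
#' model, applies presence turnover masking, and disaggregates each annual
#' density into `events_per_year` event records with mean-one lognormal
#' observation noise. Only records with positive density are emitted
#' (presence records, as field programs store them); a taxon absent from a
#' year is an observed zero at every event of that year.
#'
#' @inheritParams generate_env
#' @return A `community_table` for the site.
#' @export
generate_community <- function(config, site) {
  stopifnot(inherits(config, "synthetic_config"))
  i <- site_index(config, site)
  pool <- taxon_pool(config)
  Tn <- config$n_years
  E <- config$events_per_year
  years <- config$start_year + seq_len(Tn) - 1L

  withr::with_seed(config_seeds(config)$site[i], {
    N <- sample(seq(config$n_taxa_range[1], config$n_taxa_range[2]), 1)
    taxa <- sort(sample(pool$taxon, N))
    grp <- as.character(pool$group[match(taxa, pool$taxon)])
    gi <- match(grp, ffg_levels())

    # factor model on the log scale: site driver + group drivers + noise
    g <- rnorm(Tn)                      # shared site driver
    Fg <- matrix(rnorm(5 * Tn), 5, Tn)  # one driver per feeding group
    eps <- matrix(rnorm(N * Tn), N, Tn)
    u <- rnorm(Tn)                      # environmental driver (loadings often 0)
    z <- sqrt(config$rho_between) * matrix(g, N, Tn, byrow = TRUE) +
      sqrt(config$rho_within - config$rho_between) * Fg[gi, , drop = FALSE] +
      sqrt(1 - config$rho_within) * eps +
      config$env_loading[gi] * matrix(u, N, Tn, byrow = TRUE)

    mu <- config$density_log_mean + config$density_log_sd * rnorm(N)
    dens <- exp(mu + config$series_log_sd * z)  # N x T annual densities

    # presence mask: start present; flip state with prob turnover_rate / year
    M <- matrix(TRUE, N, Tn)
    for (t in seq(2, Tn)) {
      flip <- runif(N) < config$turnover_rate
      M[, t] <- xor(M[, t - 1], flip)
    }
    dens <- dens * M

    # event-level records with mean-one lognormal noise
    noise <- exp(rnorm(N * Tn * E, 0, config$event_noise_sd) -
                   config$event_noise_sd^2 / 2)
    long <- tibble::tibble(
      site = site,
      year = rep(rep(years, each = N), times = E),
      event = rep(seq_len(E), each = N * Tn),
      taxon = rep(taxa, times = Tn * E),
      density = rep(as.vector(dens), times = E) * noise)
    long <- long[long$density > 0, , drop = FALSE]
    long <- long[order(long$year, long$event, long$taxon), , drop = FALSE]
    as_community_table(long)
  })
}

#' Generate a full synthetic study bundle
#'
#' All sites' community tables, environmental series, the shared
#' functional-feeding-group table, and site coordinates sampled in a
#' continental-US bounding box — mutually consistent and a pure function of
#' the config (same config, same bundle).
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_study` list: `community` (`community_table`), `env`
#'   (`env_series`, both variables, all sites), `ffg` (`ffg_table`), `coords`
#'   (`site_coords`), `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sites <- synthetic_sites(config)
  coords <- withr::with_seed(config_seeds(config)$coords, {
    as_site_coords(tibble::tibble(site = sites,
                                  lat = runif(config$n_sites, 33, 46),
                                  lon = runif(config$n_sites, -122, -72)))
  })
  community <- dplyr::bind_rows(purrr::map(sites, ~generate_community(config, .x)))
  class(community) <- c("community_table", class(tibble::tibble()))
  env <- dplyr::bind_rows(purrr::map(sites, ~generate_env(config, .x)))
  class(env) <- c("env_series", class(tibble::tibble()))
  structure(list(community = community, env = env, ffg = taxon_pool(config),
                 coords = coords, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d sites, %d years x %d events, %d community rows\n",
              x$config$n_sites, x$config$n_years, x$config$events_per_year,
              nrow(x$community)))
  invisible(x)
}
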