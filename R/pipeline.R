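#' Run the full community-synchrony pipeline
#'
#' Orchestrates every stage over a multi-site study: per site, annualize the
#' community table, compute synchrony with its Monte Carlo null test,
#' temporal turnover, richness and environmental variability; then per-taxon
#' contribution z-scores, functional-feeding-group proportions, Spearman
#' screens of synchrony against the environmental and turnover summaries,
#' Moran's I spatial screens, and the crossed random-effects model of
#' z-scores. All results are computed first and written together at the end,
#' so a failing stage leaves no partial outputs; reruns with the same inputs
#' and seed produce byte-identical files.
#'
#' @param input One of: a `synthetic_config` (the study is generated first),
#'   a `synthetic_study`, a list with elements `community`, `env` (or `temp` +
#'   `discharge`), `ffg`, `coords` (validated objects), or a named list of
#'   file paths with those elements (plus optional `dialect`s applied by the
#'   readers).
#' @param out_dir Output directory (created if needed).
#' @param n_reps_community Randomizations for the community null
#'   (default 999).
#' @param n_reps_taxon Randomizations per taxon contribution (default 100).
#' @param alpha Significance level recorded in the manifest (default 0.05).
#' @param z_crit Contribution classification threshold (default 1.96).
#' @param n_perm_moran Permutations for Moran's I (default 999).
#' @param seed Master seed; all stage RNG derives from it.
#' @return Invisibly, a list of the in-memory results (`site_summary`,
#'   `contributions`, `ffg_summary`, `correlations`, `morans_i`,
#'   `mixed_model`, `manifest`) with the written file paths in
#'   `attr(, "files")`.
#' @export
run_pipeline <- function(input, out_dir,
                         n_reps_community = 999, n_reps_taxon = 100,
                         alpha = 0.05, z_crit = 1.96, n_perm_moran = 999,
                         seed = 1L) {
  study <- resolve_pipeline_input(input)
  sites <- community_sites(study$community)
  warnings_log <- character(0)
  seeds <- substream_seeds(seed, 2L * length(sites) + 1L)
  sync_seeds <- seeds[seq_along(sites)]
  contrib_seeds <- seeds[length(sites) + seq_along(sites)]
  moran_seed <- seeds[2L * length(sites) + 1L]

  stage <- function(name, site, expr) {
    tryCatch(expr, error = function(e) {
      ss_abort(sprintf("Stage `%s` failed for site `%s`: %s",
                       name, site, conditionMessage(e)),
               "streamsync_pipeline_error", parent = e)
    })
  }

  summaries <- list()
  contribs <- list()
  for (k in seq_along(sites)) {
    s <- sites[k]
    m <- stage("annualize", s, to_site_matrix(study$community, s))
    sync <- stage("synchrony", s,
                  community_null_test(m, n_reps = n_reps_community,
                                      seed = sync_seeds[k]))
    summaries[[k]] <- stage("metrics", s,
                            build_site_summary(m, study$env, study$env,
                                               study$coords, sync))
    contribs[[k]] <- stage("contributions", s,
                           all_contributions(m, n_reps = n_reps_taxon,
                                             seed = contrib_seeds[k],
                                             z_crit = z_crit))
  }
  site_summary <- dplyr::bind_rows(summaries)
  class(site_summary) <- c("site_summary", class(tibble::tibble()))
  contributions <- dplyr::bind_rows(contribs)
  contributions <- dplyr::left_join(contributions,
                                    tibble::as_tibble(study$ffg),
                                    by = "taxon")
  contributions <- dplyr::relocate(contributions, "group", .after = "taxon")
  n_degenerate <- sum(contributions$classification == "degenerate")
  if (n_degenerate > 0) {
    warnings_log <- c(warnings_log,
                      sprintf("%d degenerate (constant-column) taxa", n_degenerate))
  }
  n_unassigned <- sum(is.na(contributions$group))
  if (n_unassigned > 0) {
    warnings_log <- c(warnings_log,
                      sprintf("%d contribution rows without a feeding-group assignment",
                              n_unassigned))
  }

  ffg_summary <- withCallingHandlers(
    ffg_proportions(contributions, study$ffg),
    warning = function(w) invokeRestart("muffleWarning"))

  correlations <- dplyr::bind_rows(
    spearman_test(site_summary$phi, site_summary$temp_sd,
                  labels = c("phi", "temp_sd")),
    spearman_test(site_summary$phi, site_summary$turnover_mean,
                  labels = c("phi", "turnover_mean")),
    spearman_test(site_summary$phi, site_summary$discharge_sd,
                  labels = c("phi", "discharge_sd")))

  coords_aligned <- study$coords[match(site_summary$site, study$coords$site), ]
  moran_seeds <- substream_seeds(moran_seed, 4L)
  moran_vars <- c("temp_sd", "discharge_sd", "turnover_mean", "phi")
  morans <- dplyr::bind_rows(purrr::imap(setNames(moran_vars, moran_vars),
    function(v, nm) {
      idx <- match(nm, moran_vars)
      res <- morans_i(site_summary[[v]], coords_aligned,
                      n_perm = n_perm_moran, seed = moran_seeds[idx])
      dplyr::bind_cols(tibble::tibble(variable = nm), res)
    }))

  mm_data <- contributions[!is.na(contributions$group), ]
  mixed <- fit_ffg_mixed_model(mm_data)
  if (!mixed$converged || mixed$singular) {
    warnings_log <- c(warnings_log, sprintf(
      "mixed model: converged=%s singular=%s %s", mixed$converged,
      mixed$singular, paste(mixed$messages, collapse = "; ")))
  }
  mixed_csv <- dplyr::bind_rows(
    dplyr::mutate(tidy(mixed), component = "fixed", .before = 1),
    tibble::tibble(component = "variance",
                   term = c("site", "taxon", "residual"),
                   estimate = unlist(glance(mixed)[c("var_site", "var_taxon",
                                                     "var_residual")]),
                   std_error = NA_real_, t_value = NA_real_))

  manifest <- list(
    package = "streamsync",
    version = as.character(utils::packageVersion("streamsync")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    n_reps_community = n_reps_community, n_reps_taxon = n_reps_taxon,
    alpha = alpha, z_crit = z_crit, n_perm_moran = n_perm_moran,
    n_sites = length(sites),
    reference_level = mixed$reference_level,
    synthetic_config = if (inherits(input, "synthetic_config")) {
      unclass(input)
    } else if (inherits(study, "synthetic_study")) unclass(study$config) else NULL,
    warnings = warnings_log)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fpath <- function(f) file.path(out_dir, f)
  write_site_summary(site_summary, fpath("site_summary.csv"))
  readr::write_csv(as.data.frame(contributions), fpath("contributions.csv"))
  readr::write_csv(as.data.frame(ffg_summary), fpath("ffg_summary.csv"))
  readr::write_csv(as.data.frame(correlations), fpath("correlations.csv"))
  readr::write_csv(as.data.frame(morans), fpath("morans_i.csv"))
  readr::write_csv(as.data.frame(mixed_csv), fpath("mixed_model.csv"))
  jsonlite::write_json(manifest, fpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  out <- list(site_summary = site_summary, contributions = contributions,
              ffg_summary = ffg_summary, correlations = correlations,
              morans_i = morans, mixed_model = mixed, manifest = manifest)
  attr(out, "files") <- fpath(c("site_summary.csv", "contributions.csv",
                                "ffg_summary.csv", "correlations.csv",
                                "morans_i.csv", "mixed_model.csv",
                                "manifest.json"))
  invisible(out)
}

resolve_pipeline_input <- function(input) {
  if (inherits(input, "synthetic_config")) return(generate_study(input))
  if (inherits(input, "synthetic_study")) return(input)
  if (is.list(input)) {
    needed <- c("community", "ffg", "coords")
    if (!all(needed %in% names(input))) {
      ss_abort("Pipeline input list needs elements community, env (or temp/discharge), ffg, coords.",
               "streamsync_parameter_error")
    }
    if (is.character(input$community)) {
      env <- dplyr::bind_rows(
        read_env_series(input$temp, "temperature", input$dialect_env),
        read_env_series(input$discharge, "discharge", input$dialect_env))
      class(env) <- c("env_series", class(tibble::tibble()))
      return(list(community = read_community_long(input$community,
                                                  input$dialect_community),
                  env = env,
                  ffg = read_ffg_table(input$ffg),
                  coords = read_site_coords(input$coords)))
    }
    env <- input$env
    if (is.null(env)) {
      env <- dplyr::bind_rows(input$temp, input$discharge)
      class(env) <- c("env_series", class(tibble::tibble()))
    }
    return(list(community = input$community, env = env, ffg = input$ffg,
                coords = input$coords))
  }
  ss_abort("Unrecognized pipeline input.", "streamsync_parameter_error")
}
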