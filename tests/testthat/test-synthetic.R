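test_that("generation is a pure function of the config", {
  cfg <- tiny_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$community, s2$community)
  expect_identical(s1$env, s2$env)
  expect_identical(s1$coords, s2$coords)
  e1 <- generate_env(cfg, "S02")
  e2 <- generate_env(cfg, "S02")
  expect_identical(e1, e2)
  # standalone site generation reproduces the study's table for that site
  solo <- generate_community(cfg, "S02")
  in_study <- s1$community[s1$community$site == "S02", ]
  expect_equal(as.data.frame(solo), as.data.frame(in_study))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_taxa_range = c(20, 10)),
               class = "streamsync_config_error")
  expect_error(synthetic_config(temp_sd_range = c(5, 1)),
               class = "streamsync_config_error")
  expect_error(synthetic_config(rho_within = 0.1, rho_between = 0.5),
               class = "streamsync_config_error")
  expect_error(synthetic_config(turnover_rate = 1.2),
               class = "streamsync_config_error")
  w <- c(filterer = 0.5, gatherer = 0.5, predator = 0.5, scraper = 0,
         shredder = 0)
  expect_error(synthetic_config(ffg_weights = w),
               class = "streamsync_config_error")
})

test_that("study bundles are mutually consistent", {
  st <- generate_study(tiny_config())
  expect_true(all(st$community$taxon %in% st$ffg$taxon))
  expect_setequal(unique(st$community$site), st$coords$site)
  expect_setequal(unique(st$env$site), st$coords$site)
  expect_true(all(st$community$density >= 0))
})

test_that("environmental series hit their target variability", {
  cfg <- synthetic_config(n_sites = 4, n_years = 10,
                          n_taxa_range = c(5, 8),
                          temp_sd_range = c(6, 6),
                          discharge_sd_range = c(0.1, 0.1), seed = 12)
  for (s in synthetic_sites(cfg)) {
    es <- generate_env(cfg, s)
    sds <- env_variability(es)
    expect_equal(sds$sd[sds$variable == "temperature"], 6, tolerance = 0.1)
    expect_equal(sds$sd[sds$variable == "discharge"], 0.1, tolerance = 1e-10)
  }
  # degenerate: zero target variability gives a flat series
  flat <- synthetic_config(n_sites = 1, n_years = 3, n_taxa_range = c(3, 4),
                           temp_sd_range = c(0, 0),
                           discharge_sd_range = c(0, 0), seed = 5)
  es0 <- generate_env(flat, "S01")
  sds0 <- env_variability(es0)
  expect_equal(sds0$sd, c(0, 0), tolerance = 1e-12)
})

test_that("turnover masking produces the expected presence dynamics", {
  cfg0 <- tiny_config(turnover_rate = 0)
  m <- to_site_matrix(generate_community(cfg0, "S01"), "S01")
  expect_equal(mean_turnover(temporal_turnover(m)), 0)

  # realized turnover increases with the rate
  rates <- c(0.05, 0.2, 0.5)
  realized <- vapply(rates, function(r) {
    cfg <- synthetic_config(n_sites = 2, n_years = 10,
                            n_taxa_range = c(40, 40), turnover_rate = r,
                            seed = 31)
    mean(vapply(synthetic_sites(cfg), function(s) {
      mean_turnover(temporal_turnover(to_site_matrix(generate_community(cfg, s), s)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
})

test_that("latent correlation targets are realized on the log scale", {
  cfg <- synthetic_config(n_sites = 1, n_years = 120, events_per_year = 1,
                          n_taxa_range = c(30, 30), rho_within = 0.5,
                          rho_between = 0.2, turnover_rate = 0,
                          event_noise_sd = 0, seed = 71)
  m <- to_site_matrix(generate_community(cfg, "S01"), "S01")
  ffg <- streamsync:::taxon_pool(cfg)
  grp <- as.character(ffg$group[match(m$taxa, ffg$taxon)])
  C <- stats::cor(log(m$X))
  same <- outer(grp, grp, "==") & upper.tri(C)
  diff_g <- !outer(grp, grp, "==") & upper.tri(C)
  expect_equal(mean(C[same]), 0.5, tolerance = 0.12)
  expect_equal(mean(C[diff_g]), 0.2, tolerance = 0.15)
})

test_that("degenerate perfect correlation yields full synchrony", {
  cfg <- synthetic_config(n_sites = 1, n_years = 8, n_taxa_range = c(10, 10),
                          rho_within = 1, rho_between = 1, turnover_rate = 0,
                          event_noise_sd = 0, seed = 77)
  m <- to_site_matrix(generate_community(cfg, "S01"), "S01")
  expect_equal(community_synchrony(m)$phi, 1, tolerance = 1e-10)
})

test_that("independent taxa give synchrony near the 1/N reference", {
  cfg <- synthetic_config(n_sites = 12, n_years = 60, events_per_year = 1,
                          n_taxa_range = c(15, 15), rho_within = 0,
                          rho_between = 0, turnover_rate = 0,
                          event_noise_sd = 0, density_log_sd = 0,
                          series_log_sd = 0.3, seed = 41)
  phis <- vapply(synthetic_sites(cfg), function(s) {
    community_synchrony(to_site_matrix(generate_community(cfg, s), s))$phi
  }, numeric(1))
  expect_equal(mean(phis), expected_phi_compound_symmetry(15, 0),
               tolerance = 0.25)
})
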