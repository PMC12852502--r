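test_that("Spearman correlation honours rank structure and symmetry", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 6)
  expect_equal(spearman_test(x, exp(x))$rho, 1)      # monotone transform
  expect_equal(spearman_test(x, -x)$rho, -1)         # reversed ranks
  expect_equal(spearman_test(x, x^3)$rho, 1)
  y <- c(2, 8, 1, 4, 7, 3, 5, 6)
  expect_equal(spearman_test(x, y)$rho, spearman_test(y, x)$rho)
  expect_equal(spearman_test(x, y)$p_value, spearman_test(y, x)$p_value)
  # invariance under strictly monotone transforms of either argument
  expect_equal(spearman_test(log(x), y)$rho, spearman_test(x, y)$rho)
  expect_error(spearman_test(x, rep(1, 8)), class = "streamsync_undefined_error")
  expect_error(spearman_test(x, y[1:3]), class = "streamsync_parameter_error")
})

test_that("Moran's I equals the brute-force double sum and the ape oracle", {
  skip_if_not_installed("ape")
  withr::with_seed(77, {
    coords <- as_site_coords(data.frame(site = sprintf("P%02d", 1:10),
                                        lat = runif(10, 34, 45),
                                        lon = runif(10, -120, -75)))
    W <- streamsync:::inverse_distance_weights(coords)
    for (i in 1:5) {
      v <- rnorm(10)
      res <- morans_i(v, coords, n_perm = 99, seed = i)
      expect_equal(res$I, moran_brute(v, W), tolerance = 1e-12)
      expect_equal(res$I, ape::Moran.I(v, W)$observed, tolerance = 1e-10)
      expect_equal(res$expected_I, -1 / 9)
    }
  })
})

test_that("Moran permutation null is centred on -1/(n-1) and detects gradients", {
  withr::with_seed(88, {
    coords <- as_site_coords(data.frame(site = sprintf("P%02d", 1:12),
                                        lat = runif(12, 38, 40),
                                        lon = seq(-120, -76, length.out = 12)))
    W <- streamsync:::inverse_distance_weights(coords)
    # null mean over permutations of exchangeable values
    v <- rnorm(12)
    perms <- vapply(1:2000, function(i) {
      streamsync:::moran_stat(v[sample.int(12)], W)
    }, numeric(1))
    expect_equal(mean(perms), -1 / 11, tolerance = 0.25)
    # smooth monotone function of longitude -> positive autocorrelation
    grad <- morans_i(sin(seq(0, 1.5, length.out = 12)) + coords$lon / 50,
                     coords, n_perm = 499, seed = 3)
    expect_gt(grad$I, grad$expected_I)
    expect_lt(grad$p_value, 0.05)
  })
  # coincident coordinates are an explicit error naming the pair
  dup <- as_site_coords(data.frame(site = c("A", "B", "C"),
                                   lat = c(40, 40, 41), lon = c(-100, -100, -99)))
  err <- expect_error(morans_i(c(1, 2, 3), dup, n_perm = 9),
                      class = "streamsync_validation_error")
  expect_match(conditionMessage(err), "A and B")
})

test_that("feeding-group proportions count classifications exactly", {
  contr <- tibble::tibble(
    site = "S", taxon = sprintf("t%d", 1:8),
    z = c(3, 3, 3, 3, 3, -3, 0, 0),
    phi_obs = 0.5, null_mean = 0.4, null_sd = 0.05, n_reps = 100,
    classification = c(rep("positive", 5), "negative", "nonsignificant",
                       "degenerate"))
  ffg <- as_ffg_table(data.frame(
    taxon = sprintf("t%d", 1:8),
    group = c(rep("scraper", 4), rep("gatherer", 4))))
  props <- ffg_proportions(contr, ffg)
  expect_equal(props$prop_positive[props$group == "scraper"], 1)
  expect_equal(props$prop_positive[props$group == "gatherer"], 0.25)
  expect_equal(props$prop_negative[props$group == "gatherer"], 0.25)
  # conservation: group sizes add up to the assigned taxa
  expect_equal(sum(props$n_taxa), 8)
  # empty groups flagged with NA proportions
  expect_true(is.na(props$prop_positive[props$group == "filterer"]))
  expect_equal(props$n_taxa[props$group == "filterer"], 0)

  # unassigned taxa excluded but counted
  ffg2 <- as_ffg_table(data.frame(taxon = sprintf("t%d", 1:6),
                                  group = rep("scraper", 6)))
  expect_warning(props2 <- ffg_proportions(contr, ffg2), "2 contribution")
  expect_equal(attr(props2, "n_unassigned"), 2)
  expect_equal(sum(props2$n_taxa), 6)
})

test_that("mixed model degenerates to group means on balanced noise-free data", {
  groups <- c("filterer", "gatherer", "predator", "scraper", "shredder")
  df <- expand.grid(site = sprintf("s%d", 1:4), taxon = sprintf("g%02d", 1:20),
                    stringsAsFactors = FALSE)
  df$group <- groups[(match(df$taxon, sort(unique(df$taxon))) - 1) %% 5 + 1]
  means <- c(filterer = 0, gatherer = 1, predator = 2, scraper = 3, shredder = 4)
  df$z <- means[df$group] + rep(c(-0.01, 0.01), length.out = nrow(df))
  fit <- fit_ffg_mixed_model(df)
  expect_equal(fit$reference_level, "filterer")
  td <- tidy(fit)
  est <- unname(td$estimate[match(paste0("group", groups[-1]), td$term)])
  expect_equal(est, unname(means[-1]), tolerance = 1e-3)
  expect_equal(td$t_value, td$estimate / td$std_error)
  gl <- glance(fit)
  expect_true(all(c("var_site", "var_taxon", "var_residual") %in% names(gl)))
  expect_true(all(stats::na.omit(unlist(gl[1:3])) >= 0))
})

test_that("mixed model refuses degenerate designs", {
  df <- data.frame(z = rnorm(10), site = rep(c("a", "b"), 5),
                   taxon = sprintf("t%d", 1:10), group = "scraper")
  expect_error(fit_ffg_mixed_model(df), class = "streamsync_parameter_error")
  df2 <- data.frame(z = rnorm(10), site = "a", taxon = sprintf("t%d", 1:10),
                    group = rep(c("scraper", "shredder"), 5))
  expect_error(fit_ffg_mixed_model(df2), class = "streamsync_parameter_error")
})
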