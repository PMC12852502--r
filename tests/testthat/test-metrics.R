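test_that("turnover matches exhaustive set arithmetic on presence sets", {
  # {a,b,c} -> {b,c,d}: one gain, one loss, union of four
  X <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 1))
  m <- community_matrix(X, taxa = c("a", "b", "c", "d"))
  tr <- temporal_turnover(m)
  expect_equal(tr$gains, 1)
  expect_equal(tr$losses, 1)
  expect_equal(tr$union_richness, 4)
  expect_equal(tr$turnover, 0.5)
  expect_equal(mean_turnover(tr), 0.5)

  # identical consecutive communities
  same <- community_matrix(rbind(c(1, 2), c(3, 4), c(1, 1)))
  expect_equal(temporal_turnover(same)$turnover, c(0, 0))

  # complete replacement {a,b} -> {c,d}
  repl <- community_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(temporal_turnover(repl)$turnover, 1)

  # symmetry in the two years of a pair
  rev <- community_matrix(X[2:1, , drop = FALSE], taxa = c("a", "b", "c", "d"))
  expect_equal(temporal_turnover(rev)$turnover, tr$turnover)
})

test_that("turnover stays in [0,1] over random presence histories", {
  withr::with_seed(21, {
    for (i in 1:20) {
      m <- random_matrix(T = sample(3:9, 1), N = sample(3:10, 1))
      # sparsify to create real gains/losses
      X <- m$X * (matrix(runif(length(m$X)), nrow(m$X)) > 0.4)
      keep <- colSums(X) > 0
      X <- X[, keep, drop = FALSE]
      if (ncol(X) == 0) next
      tr <- temporal_turnover(community_matrix(X))
      expect_true(all(tr$turnover >= 0 & tr$turnover <= 1))
      expect_equal(mean_turnover(tr), mean(tr$turnover))
    }
  })
})

test_that("richness counts taxa ever present", {
  expect_equal(richness(community_matrix(matrix(1:6, 2, 3))), 3)
})

test_that("Simpson diversity matches the 1 - sum(p^2) definition", {
  expect_equal(simpson_diversity(c(5)), 0)              # single taxon
  expect_equal(simpson_diversity(c(2, 2)), 0.5)         # even pair
  expect_equal(simpson_diversity(c(0.5, 0.3, 0.2)), 0.62)
  # oracle: direct formula on random abundance vectors
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- stats::rlnorm(sample(2:12, 1))
      p <- x / sum(x)
      expect_equal(simpson_diversity(x), 1 - sum(p^2), tolerance = 1e-12)
      expect_lte(simpson_diversity(x), 1 - 1 / length(x) + 1e-12)
    }
  })
  expect_error(simpson_diversity(c(0, 0)), class = "streamsync_undefined_error")
})

test_that("environmental variability is the sample SD with its invariances", {
  expect_equal(env_variability(c(3, 3, 3)), 0)
  expect_equal(env_variability(c(1, 2, 3)), 1)
  x <- c(4.2, 9.1, 0.3, 7.7)
  expect_equal(env_variability(x + 100), env_variability(x))     # translation
  expect_equal(env_variability(x * 2.5), 2.5 * env_variability(x))  # scaling
  expect_error(env_variability(5), class = "streamsync_insufficient_data_error")

  es <- as_env_series(tibble::tibble(site = rep(c("A", "B"), each = 3),
                                     timestamp = rep(1:3, 2),
                                     value = c(1, 2, 3, 5, 5, 5)),
                      "temperature")
  tab <- env_variability(es)
  expect_equal(tab$sd[tab$site == "A"], 1)
  expect_equal(tab$sd[tab$site == "B"], 0)
})

test_that("build_site_summary assembles finite fields and checks identity", {
  m <- to_site_matrix(toy_two_site_table(), "A")
  es <- as_env_series(tibble::tibble(
    site = "A",
    variable = rep(c("temperature", "discharge"), each = 4),
    timestamp = rep(1:4, 2),
    value = c(10, 12, 9, 11, 0.1, 0.3, 0.2, 0.15)))
  coords <- as_site_coords(data.frame(site = "A", lat = 40, lon = -100))
  sync <- community_null_test(m, n_reps = 99, seed = 2)
  row <- build_site_summary(m, es, es, coords, sync)
  expect_equal(nrow(row), 1)
  expect_true(all(vapply(row[-1], function(v) is.finite(as.numeric(v)),
                         logical(1))))
  expect_equal(row$S, richness(m))
  expect_equal(row$phi, sync$phi)

  sync$site_id <- "B"
  expect_error(build_site_summary(m, es, es, coords, sync),
               class = "streamsync_consistency_error")
})
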