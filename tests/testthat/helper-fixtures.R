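# Fixtures built in code: toy tables and simulators shared across test files.

toy_community_df <- function() {
  tibble::tibble(
    site = "S1",
    year = rep(c(2020L, 2021L), each = 3),
    event = rep(1:3, times = 2),
    taxon = rep(c("Baetis", "Simulium", "Baetis"), 2),
    density = c(1, 5, 2, 3, 4, 6))
}

# A community table with two sites, three years, two events, four taxa.
toy_two_site_table <- function() {
  grid <- expand.grid(site = c("A", "B"), year = 2019:2021, event = 1:2,
                      taxon = c("t1", "t2", "t3", "t4"),
                      stringsAsFactors = FALSE)
  grid$density <- seq_len(nrow(grid)) %% 7 + 1
  as_community_table(grid)
}

# Equal-variance compound-symmetry community: N unit-variance series with
# common pairwise correlation rho, shifted so densities stay positive.
cs_matrix <- function(N, T, rho, mean = 20) {
  g <- rnorm(T)
  eps <- matrix(rnorm(T * N), T, N)
  X <- mean + sqrt(rho) * g + sqrt(1 - rho) * eps
  community_matrix(pmax(X, 0))
}

# Random non-negative community matrix for property tests.
random_matrix <- function(T = 8, N = 6) {
  community_matrix(matrix(stats::rlnorm(T * N, meanlog = 1), T, N))
}

# Brute-force synchrony: form the summed series explicitly and apply the
# definition with an arbitrary (but consistent) variance divisor.
phi_brute <- function(X, divisor = c("sample", "population")) {
  divisor <- match.arg(divisor)
  vfun <- if (divisor == "sample") stats::var else function(x) mean((x - mean(x))^2)
  total <- numeric(nrow(X))
  for (t in seq_len(nrow(X))) total[t] <- sum(X[t, ])
  sds <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) sds[j] <- sqrt(vfun(X[, j]))
  vfun(total) / sum(sds)^2
}

# Brute-force Moran's I as an explicit O(n^2) double sum.
moran_brute <- function(v, W) {
  n <- length(v)
  z <- v - mean(v)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + W[i, j] * z[i] * z[j]
  (n / sum(W)) * acc / sum(z^2)
}

tiny_config <- function(...) {
  synthetic_config(n_sites = 3, n_years = 6, events_per_year = 3,
                   n_taxa_range = c(10, 15), seed = 99, ...)
}
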