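# Internal helpers shared across modules.

# Classed condition helpers so callers can distinguish user/data errors.
ss_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "streamsync_error"), ...)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    ss_abort(sprintf("`%s` must be a single integer >= %d.", name, min),
             "streamsync_parameter_error")
  }
  as.integer(x)
}

# Draw reproducible substream seeds from a master seed without disturbing the
# caller's RNG state. Seeds are drawn up-front in a fixed order, so results do
# not depend on the order in which substreams are later consumed.
substream_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Per-replicate within-block permutation indices: a T x R matrix whose columns
# are independent permutations of 1:T, obtained from a single order() call.
block_permutations <- function(T, R) {
  block <- rep.int(seq_len(R), rep.int(T, R))
  o <- order(block, runif(T * R))
  matrix(o - (block - 1L) * T, nrow = T, ncol = R)
}

# Column variances with the sample (n - 1) divisor, vectorized.
col_vars <- function(M) {
  n <- nrow(M)
  cm <- colMeans(M)
  (colSums(M * M) - n * cm * cm) / (n - 1)
}

ffg_levels <- function() c("filterer", "gatherer", "predator", "scraper", "shredder")
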