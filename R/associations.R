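#' Spearman rank correlation screen
#'
#' Spearman's rho between two site-level quantities (e.g. synchrony against
#' temperature variability): the Pearson correlation of midranks, with a
#' two-sided p-value from the t-approximation on n - 2 degrees of freedom
#' (ties make the exact distribution unavailable; the approximation is the
#' standard choice at these sample sizes).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @param labels Optional length-2 character vector naming the pair in the
#'   output.
#' @return A one-row tibble: `variable_pair`, `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) {
    ss_abort("`x` and `y` must have equal length.", "streamsync_parameter_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    ss_abort("At least 3 complete pairs are needed.",
             "streamsync_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    ss_abort("Spearman correlation is undefined for a constant vector.",
             "streamsync_undefined_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(variable_pair = paste(labels, collapse = " vs "),
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Tests whether a site-level quantity (synchrony, turnover, environmental
#' variability) is spatially structured:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij}(v_i - \bar v)(v_j - \bar v)}{\sum_i (v_i - \bar v)^2}}
#' with expectation `-1/(n - 1)` under exchangeability. Weights are inverse
#' great-circle (haversine) distances with a zero diagonal, row-standardized.
#' The p-value comes from randomly permuting values over locations, two-sided
#' around the expectation:
#' `p = (1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (n_perm + 1)`.
#'
#' @param values Numeric vector, one value per site, not constant.
#' @param coords A `site_coords` tibble aligned with `values` (same order) or
#'   a data frame with `site`, `lat`, `lon`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble: `I`, `expected_I`, `p_value`, `n`, `weight_spec`.
#' @export
morans_i <- function(values, coords, n_perm = 999, seed = 1L) {
  n <- length(values)
  if (n < 3) {
    ss_abort("Moran's I needs at least 3 sites.",
             "streamsync_insufficient_data_error")
  }
  if (nrow(coords) != n) {
    ss_abort("`values` and `coords` must have the same length.",
             "streamsync_parameter_error")
  }
  if (sd(values) == 0) {
    ss_abort("Moran's I is undefined for constant values.",
             "streamsync_undefined_error")
  }
  W <- inverse_distance_weights(coords)
  n_perm <- stopifnot_scalar_count(n_perm, "n_perm")

  I_obs <- moran_stat(values, W)
  e_i <- -1 / (n - 1)
  I_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(r) moran_stat(values[sample.int(n)], W),
           numeric(1))
  })
  p <- (1 + sum(abs(I_perm - e_i) >= abs(I_obs - e_i))) / (n_perm + 1)
  tibble::tibble(I = I_obs, expected_I = e_i, p_value = p, n = n,
                 weight_spec = "inverse haversine distance, row-standardized")
}

# I for a row-standardized weight matrix (sum(W) = n, so the n/sum(W)
# normalization cancels); written as the full double sum via a quadratic form.
moran_stat <- function(v, W) {
  z <- v - mean(v)
  (length(v) / sum(W)) * as.numeric(z %*% W %*% z) / sum(z^2)
}

inverse_distance_weights <- function(coords) {
  n <- nrow(coords)
  pts <- cbind(coords$lon, coords$lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[(i + 1):n, , drop = FALSE])
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  if (any(D[upper.tri(D)] == 0)) {
    idx <- which(upper.tri(D) & D == 0, arr.ind = TRUE)[1, ]
    ss_abort(sprintf(
      "Sites %s and %s have coincident coordinates: inverse-distance weight is infinite.",
      coords$site[idx[1]], coords$site[idx[2]]),
      "streamsync_validation_error")
  }
  W <- 1 / D
  diag(W) <- 0
  W / rowSums(W)
}

#' Functional-feeding-group contribution proportions
#'
#' Aggregates per-taxon contribution classifications by functional feeding
#' group: for each of the five groups, the number of classified taxa and the
#' proportions with significant positive and negative contributions.
#' Degenerate taxa stay in the denominator. Taxa without an assignment are
#' excluded from the group summaries but counted in the `n_unassigned`
#' attribute (and a warning).
#'
#' @param contributions A `taxon_contributions` tibble ([all_contributions()]),
#'   possibly spanning several sites. If it already carries a `group` column
#'   that assignment is used directly.
#' @param ffg An `ffg_table`; may be `NULL` when `contributions` has `group`.
#' @return A tibble with one row per group: `group`, `n_taxa`,
#'   `prop_positive`, `prop_negative` (NA for empty groups), with attribute
#'   `n_unassigned`.
#' @export
ffg_proportions <- function(contributions, ffg = NULL) {
  stopifnot(is.data.frame(contributions))
  if ("group" %in% names(contributions)) {
    joined <- contributions
  } else {
    stopifnot(inherits(ffg, "ffg_table"))
    joined <- dplyr::left_join(contributions, ffg, by = "taxon")
  }
  n_unassigned <- sum(is.na(joined$group))
  if (n_unassigned > 0) {
    warn(sprintf("%d contribution row(s) have no functional feeding group assignment; excluded.",
                 n_unassigned))
  }
  joined <- joined[!is.na(joined$group), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(joined, group = factor(.data$group, levels = ffg_levels())),
    n_taxa = dplyr::n(),
    prop_positive = mean(.data$classification == "positive"),
    prop_negative = mean(.data$classification == "negative"),
    .groups = "drop")
  out <- tidyr::complete(out, group,
                         fill = list(n_taxa = 0L, prop_positive = NA_real_,
                                     prop_negative = NA_real_))
  out$prop_positive[out$n_taxa == 0] <- NA_real_
  out$prop_negative[out$n_taxa == 0] <- NA_real_
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Crossed random-effects model of contribution z-scores
#'
#' Taxa recur across sites, so group-level differences in synchrony
#' contributions are tested with a linear mixed model: z-scores as the
#' response, functional feeding group as the fixed effect (treatment coding,
#' alphabetical reference level = filterer), and crossed random intercepts
#' for site and for taxon, fitted by REML via \pkg{lme4}.
#'
#' @param contributions A data frame with columns `z`, `site`, `taxon`, and
#'   `group` (e.g. [all_contributions()] joined to an `ffg_table`).
#' @return An `ffg_lmm` object wrapping the `lmerMod` fit, with `tidy()`
#'   (fixed effects: estimate, SE, t) and `glance()` (variance components,
#'   convergence flag) methods.
#' @export
fit_ffg_mixed_model <- function(contributions) {
  required <- c("z", "site", "taxon", "group")
  missing <- setdiff(required, names(contributions))
  if (length(missing) > 0) {
    ss_abort(sprintf("Contributions are missing column(s): %s.",
                     paste(missing, collapse = ", ")),
             "streamsync_format_error")
  }
  df <- tibble::as_tibble(contributions)[required]
  df <- df[is.finite(df$z), , drop = FALSE]
  df$group <- factor(as.character(df$group))
  if (nlevels(droplevels(df$group)) < 2) {
    ss_abort("Only one functional feeding group present: compare group means directly instead of fitting a mixed model.",
             "streamsync_parameter_error")
  }
  if (length(unique(df$site)) < 2) {
    ss_abort("At least 2 sites are required for a site random effect.",
             "streamsync_parameter_error")
  }
  df$group <- droplevels(df$group)

  fit <- lme4::lmer(z ~ group + (1 | site) + (1 | taxon), data = df,
                    REML = TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  structure(
    list(fit = fit,
         reference_level = levels(df$group)[1],
         n_obs = nrow(df),
         converged = length(msgs) == 0,
         singular = lme4::isSingular(fit),
         messages = msgs %||% character(0)),
    class = "ffg_lmm")
}

#' @export
print.ffg_lmm <- function(x, ...) {
  cat(sprintf("<ffg_lmm> z ~ group + (1|site) + (1|taxon), REML; n = %d, reference = %s\n",
              x$n_obs, x$reference_level))
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed effects of a contribution mixed model
#'
#' @param x An `ffg_lmm`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `t_value`.
#' @method tidy ffg_lmm
#' @export
tidy.ffg_lmm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std_error = cf[, "Std. Error"], t_value = cf[, "t value"])
}

#' @rdname tidy.ffg_lmm
#' @return `glance()`: one-row tibble with variance components
#'   (`var_site`, `var_taxon`, `var_residual`), `n_obs`, `reference_level`,
#'   `converged`, `singular`.
#' @method glance ffg_lmm
#' @export
glance.ffg_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(var_site = getv("site"), var_taxon = getv("taxon"),
                 var_residual = getv("Residual"), n_obs = x$n_obs,
                 reference_level = x$reference_level,
                 converged = x$converged, singular = x$singular)
}
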