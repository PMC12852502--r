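#' Community synchrony (variance-ratio statistic)
#'
#' The Loreau-de Mazancourt synchrony statistic for a years-by-taxa abundance
#' matrix:
#' \deqn{\phi = \frac{\mathrm{var}\left(\sum_i x_i(t)\right)}{\left(\sum_i \mathrm{sd}(x_i)\right)^2}}
#' the temporal variance of total community abundance divided by the squared
#' sum of the per-taxon temporal standard deviations. \eqn{\phi = 1} when all
#' taxa fluctuate in perfect proportion, \eqn{\phi = 0} when fluctuations
#' compensate exactly so the total is constant; by the Cauchy-Schwarz
#' inequality \eqn{0 \le \phi \le 1} always. Sample (T - 1) variances are used
#' throughout; \eqn{\phi} is invariant to that choice as long as it is
#' consistent, and to multiplying the matrix by any positive constant.
#'
#' Taxa with zero temporal variance contribute nothing to either the
#' numerator's variability or the denominator sum; they are retained in the
#' community (not dropped). If every taxon is constant the statistic is the
#' undefined ratio 0/0 and an error is raised.
#'
#' @param matrix A `community_matrix` (see [to_site_matrix()],
#'   [community_matrix()]), or a bare numeric T x N matrix.
#' @return A `synchrony_result`: list with `phi`, `var_total` (variance of the
#'   summed series), `sd_species` (named per-taxon SDs), `n_taxa`, `n_years`,
#'   and `NA` placeholders for the null-test fields filled by
#'   [community_null_test()].
#' @examples
#' community_synchrony(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))$phi   # 1
#' community_synchrony(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))$phi   # 0
#' @seealso [community_null_test()], [expected_phi_compound_symmetry()]
#' @export
community_synchrony <- function(matrix) {
  m <- coerce_community_matrix(matrix)
  X <- m$X
  sds <- sqrt(pmax(col_vars(X), 0))
  denom <- sum(sds)^2
  if (denom == 0) {
    ss_abort("All taxa are constant over time: synchrony is the undefined ratio 0/0.",
             "streamsync_undefined_synchrony_error")
  }
  v_tot <- var(rowSums(X))
  phi <- v_tot / denom
  # guard against floating-point overshoot at the phi = 1 boundary
  phi <- min(max(phi, 0), 1)
  structure(
    list(phi = phi, var_total = v_tot, sd_species = setNames(sds, m$taxa),
         n_taxa = ncol(X), n_years = nrow(X),
         p_value = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
         n_reps = NA_integer_, seed = NA_integer_, site_id = m$site_id),
    class = "synchrony_result")
}

coerce_community_matrix <- function(x) {
  if (inherits(x, "community_matrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(community_matrix(x))
  ss_abort("Expected a community_matrix or a numeric matrix.",
           "streamsync_parameter_error")
}

#' Expected synchrony of an equal-variance compound-symmetry community
#'
#' Closed-form reference value used as an analytic oracle: for N taxa with
#' equal temporal variance and constant pairwise correlation rho, the
#' variance-ratio synchrony is exactly
#' \deqn{\phi = \frac{1 + (N - 1)\rho}{N}.}
#' Independence gives \eqn{1/N}; full correlation gives 1.
#'
#' @param n_taxa Number of taxa (N >= 1).
#' @param rho Common pairwise correlation, in `[-1/(N-1), 1]` (the
#'   positive-semidefinite range).
#' @return The expected phi, a scalar in `[0, 1]`.
#' @export
expected_phi_compound_symmetry <- function(n_taxa, rho) {
  n_taxa <- stopifnot_scalar_count(n_taxa, "n_taxa")
  lower <- if (n_taxa > 1) -1 / (n_taxa - 1) else -1
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < lower - 1e-12 || rho > 1) {
    ss_abort(sprintf("`rho` must lie in [%.4f, 1] for n_taxa = %d.", lower, n_taxa),
             "streamsync_domain_error")
  }
  (1 + (n_taxa - 1) * rho) / n_taxa
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result> site %s: phi = %.4f (%d taxa, %d years)\n",
              x$site_id %||% "?", x$phi, x$n_taxa, x$n_years))
  if (!is.na(x$p_value)) {
    cat(sprintf("  null: mean %.4f, sd %.4f (%d reps); one-tailed p = %.4g\n",
                x$null_mean, x$null_sd, x$n_reps, x$p_value))
  }
  invisible(x)
}

#' Tidy a synchrony result
#'
#' @param x A `synchrony_result`.
#' @param ... Unused.
#' @return A one-row tibble with phi, the null summary, and the p-value.
#' @method tidy synchrony_result
#' @export
tidy.synchrony_result <- function(x, ...) {
  tibble::tibble(site = x$site_id %||% NA_character_,
                 phi = x$phi, var_total = x$var_total,
                 n_taxa = x$n_taxa, n_years = x$n_years,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 n_reps = x$n_reps, p_value = x$p_value)
}

#' @rdname tidy.synchrony_result
#' @method glance synchrony_result
#' @export
glance.synchrony_result <- function(x, ...) tidy.synchrony_result(x, ...)
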