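#' Published site-level summaries for the 18 NEON wadeable streams
#'
#' The bundled site summary table for the 18 NEON core wadeable-stream sites
#' sampled 2014-2022: coordinates, genus richness `S`, temperature and
#' discharge variability (SD of the full series), mean annual temporal
#' turnover, community synchrony `phi`, and the Monte Carlo p-value. Values
#' are as printed at the source's precision; p-values reported there as
#' "< 0.001" are stored as 0.001 (the add-one lower bound at 999
#' randomizations). Useful for exercising the association and metrics stages
#' on real site-level numbers without any download.
#'
#' @return A `site_summary` tibble with 18 rows.
#' @examples
#' neon_site_summary()
#' @export
neon_site_summary <- function() {
  path <- system.file("extdata", "neon_site_summary.csv",
                      package = "streamsync", mustWork = TRUE)
  read_site_summary(path)
}
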