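#' Bundled Xingtai case-study tables
#'
#' The package ships the Xingtai city (2006-2017) land ecological security
#' case as plain-text fixtures: the 24-indicator DPSIR metadata, the six
#' expert 0/1/2 comparison matrices (criterion layer plus one per DPSIR
#' layer), the case's entropy weights, the composite security series with
#' layer subscores, and the per-year top-five obstacle rankings. The raw
#' indicator panel underlying the case is not distributed with it, so the
#' entropy weights, series and rankings are carried as reference *data* (for
#' reproducing downstream bookkeeping and for regression tests), not as
#' recomputable results; the comparison matrices, by contrast, fully
#' determine the subjective weights.
#'
#' @return list with elements `metadata` ([indicator_system()]),
#'   `comparisons` (named list of [comparison_matrix()]; element
#'   `criterion` plus `D`, `P`, `S`, `I`, `R`), `entropy_weights` (named
#'   vector), `security_series` (data frame `year`, `T`, `D`, `P`, `S`, `I`,
#'   `R`), and `obstacle_top5` (data frame `year`, `rank`, `code`,
#'   `obstacle_pct`).
#' @export
#' @examples
#' xt <- xingtai_case()
#' nrow(xt$metadata)
xingtai_case <- function() {
  path <- function(f) system.file("extdata", f, package = "landsec", mustWork = TRUE)
  manifest <- jsonlite::read_json(path("xingtai_matrices.json"), simplifyVector = TRUE)
  comparisons <- lapply(manifest, function(f) read_comparison_matrix(path(f)))
  list(
    metadata = read_indicator_metadata(path("xingtai_indicators.csv")),
    comparisons = comparisons,
    entropy_weights = read_entropy_weights(path("xingtai_entropy_weights.csv")),
    security_series = utils::read.csv(path("xingtai_security_series.csv"),
                                      check.names = FALSE),
    obstacle_top5 = utils::read.csv(path("xingtai_obstacle_top5.csv"),
                                    check.names = FALSE)
  )
}
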