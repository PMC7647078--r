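#' Index deviations from the ideal state
#'
#' `N[i, j] = 1 - Y[i, j]`: how far each indicator falls short of its ideal
#' (fully secure) normalized value in each year.
#'
#' @param Y a `normalized_panel` or matrix in \[0, 1\].
#' @return deviation matrix `N` in \[0, 1\].
#' @export
deviation_matrix <- function(Y) 1 - as_Y(Y)

#' Obstacle degrees
#'
#' Each indicator's share of a year's total security shortfall, weighting
#' deviation by factor contribution (the combined weight):
#' `F[i, j] = N[i, j] * A_i / sum_i N[i, j] * A_i`. Columns sum to 1. A year
#' with no deviation at all (perfect security) has no defined obstacle
#' profile and is reported as all-zero with a warning.
#'
#' @param N deviation matrix from [deviation_matrix()].
#' @param A named combined weight vector aligned with the rows of `N`.
#' @return obstacle-degree matrix `F` (fractions; multiply by 100 for %).
#' @export
obstacle_degrees <- function(N, A) {
  N <- as.matrix(N)
  if (nrow(N) != length(A)) stop_("weight length does not match deviation rows")
  if (!is.null(rownames(N)) && !is.null(names(A)) && !identical(rownames(N), names(A)))
    stop_("weight codes do not match deviation row codes")
  FA <- N * A
  tot <- colSums(FA)
  zero <- tot == 0
  if (any(zero))
    warn_("year(s) with zero total deviation (perfect security): %s",
          toString(colnames(N)[zero] %||% which(zero)))
  Fm <- sweep(FA, 2, ifelse(zero, 1, tot), "/")
  Fm
}

#' Top-k obstacle factors per year
#'
#' Ranks indicators by obstacle degree within each year. Exact ties are
#' broken deterministically by canonical DPSIR layer order (D, P, S, I, R)
#' then numeric code index, and flagged in the `tie` column.
#'
#' @param F obstacle-degree matrix (codes as rownames, years as colnames).
#' @param k how many factors to report per year (default 5).
#' @param digits decimals for the reported percentage.
#' @return data frame `year`, `rank`, `code`, `obstacle_pct`, `tie`.
#' @export
top_obstacles <- function(F, k = 5, digits = 2) {
  F <- as.matrix(F)
  if (k < 1 || k > nrow(F)) stop_("k must be between 1 and the indicator count")
  codes <- rownames(F) %||% as.character(seq_len(nrow(F)))
  years <- colnames(F) %||% as.character(seq_len(ncol(F)))
  out <- lapply(seq_len(ncol(F)), function(j) {
    f <- F[, j]
    ord <- order(-f, match(code_layer(codes), .layers), code_index(codes), codes)
    sel <- ord[seq_len(k)]
    dupval <- f[sel] %in% f[duplicated(f)]
    data.frame(year = years[j], rank = seq_len(k), code = codes[sel],
               obstacle_pct = round_half_up(100 * f[sel], digits),
               tie = dupval, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Frequency of top-k obstacle factors across years
#'
#' Counts how many years each factor appears in the top-k ranking and the
#' corresponding share of years.
#'
#' @param rankings data frame from [top_obstacles()] (columns `year`, `code`).
#' @param n_years number of years; defaults to the distinct years present.
#' @param digits decimals for the percentage.
#' @return data frame `code`, `count`, `pct`, in canonical code order.
#' @export
obstacle_frequency <- function(rankings, n_years = length(unique(rankings$year)),
                               digits = 2) {
  if (!nrow(rankings)) stop_("rankings are empty")
  counts <- table(rankings$code)
  df <- data.frame(code = names(counts), count = as.integer(counts),
                   row.names = NULL)
  df <- df[order_codes(df$code), , drop = FALSE]
  df$pct <- round_half_up(df$count / n_years * 100, digits)
  rownames(df) <- NULL
  df
}

#' Full obstacle diagnosis of a normalized panel
#'
#' Convenience wrapper: deviations, obstacle degrees, per-year top-k ranking
#' and the cross-year frequency summary, plus criterion-layer obstacle sums.
#'
#' @param Y a `normalized_panel`.
#' @param A named combined weight vector aligned with the panel codes.
#' @param k top-k size (default 5).
#' @return list with `N`, `F`, `top`, `frequency` and `layer_obstacles`
#'   (layers x years, each year summing to 1).
#' @export
obstacle_diagnosis <- function(Y, A, k = 5) {
  stopifnot(inherits(Y, "normalized_panel"))
  N <- deviation_matrix(Y)
  Fm <- obstacle_degrees(N, A)
  layer <- factor(Y$metadata$layer, levels = .layers)
  lo <- rowsum(Fm, layer)
  list(N = N, F = Fm,
       top = top_obstacles(Fm, k = k),
       frequency = obstacle_frequency(top_obstacles(Fm, k = k)),
       layer_obstacles = lo[intersect(.layers, rownames(lo)), , drop = FALSE])
}
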